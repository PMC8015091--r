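# Sequence-identity stage: pairwise identity fractions computed from a
# supplied multiple alignment (e.g. MUSCLE output for mitochondrial genomes),
# feeding the same clustering and tree machinery as the PCC matrix.

#' Multiple-alignment container
#'
#' Equal-length aligned rows over \code{{A,C,G,T,N,-}} (uppercase-normalized)
#' with unique species labels.
#'
#' @param rows character vector of aligned sequences.
#' @param labels character vector of species labels, same length.
#' @return object of class \code{alignment_block}: list with \code{labels}
#'   and \code{rows}.
#' @export
alignment_block <- function(rows, labels) {
  if (!is.character(rows) || length(rows) == 0)
    stop("invalid-input: alignment needs at least one row", call. = FALSE)
  if (length(labels) != length(rows) || anyDuplicated(labels))
    stop("invalid-input: labels must be unique and match rows", call. = FALSE)
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1 || w == 0)
    stop("invalid-input: alignment rows must have equal, non-zero length", call. = FALSE)
  structure(list(labels = unname(labels), rows = unname(rows)),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("<alignment_block> ", length(x$rows), " sequences x ",
      nchar(x$rows[1]), " columns\n", sep = "")
  invisible(x)
}

#' Pairwise identity of two aligned rows
#'
#' Fraction of counted columns where the two letters are identical. The
#' default dialect: columns where both rows are gaps are excluded from the
#' denominator; a gap against a letter counts as a mismatch; \code{N}
#' matches nothing (even another \code{N}). Each rule can be switched to
#' compare alternative identity-matrix dialects.
#'
#' @param row_a,row_b aligned strings of equal length.
#' @param exclude_both_gaps drop both-gap columns from the denominator
#'   (default \code{TRUE}; otherwise they count as identical columns).
#' @param gap_mismatch count gap-vs-letter columns as mismatches (default
#'   \code{TRUE}; otherwise such columns are excluded).
#' @param n_mismatch treat \code{N} as matching nothing (default
#'   \code{TRUE}; otherwise \code{N} columns are excluded).
#' @return identity fraction in \eqn{[0, 1]}.
#' @examples
#' identity_pair("ACGT", "ACGA")   # 0.75
#' identity_pair("AC-T", "A--T")   # 2/3: both-gap column dropped
#' @export
identity_pair <- function(row_a, row_b, exclude_both_gaps = TRUE,
                          gap_mismatch = TRUE, n_mismatch = TRUE) {
  if (nchar(row_a) != nchar(row_b))
    stop("invalid-input: aligned rows differ in length", call. = FALSE)
  a <- strsplit(toupper(row_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(row_b), "", fixed = TRUE)[[1]]
  .identity_chars(a, b, exclude_both_gaps, gap_mismatch, n_mismatch)
}

.identity_chars <- function(a, b, exclude_both_gaps, gap_mismatch, n_mismatch) {
  gap_a <- a == "-"
  gap_b <- b == "-"
  counted <- rep(TRUE, length(a))
  if (exclude_both_gaps) counted <- counted & !(gap_a & gap_b)
  if (!gap_mismatch) counted <- counted & !xor(gap_a, gap_b)
  has_n <- a == "N" | b == "N"
  if (!n_mismatch) counted <- counted & !has_n
  if (!any(counted))
    stop("degenerate-input: no counted columns between the two rows", call. = FALSE)
  match <- a == b
  if (n_mismatch) match <- match & !has_n
  sum(match & counted) / sum(counted)
}

#' Pairwise sequence-identity matrix from a multiple alignment
#'
#' Applies [identity_pair()] to every pair of rows, yielding a symmetric
#' matrix with unit diagonal of kind \code{"identity"}.
#'
#' @param alignment an [alignment_block()].
#' @inheritParams identity_pair
#' @return a [similarity_matrix()] of kind \code{"identity"}.
#' @export
identity_matrix <- function(alignment, exclude_both_gaps = TRUE,
                            gap_mismatch = TRUE, n_mismatch = TRUE) {
  stopifnot(inherits(alignment, "alignment_block"))
  n <- length(alignment$rows)
  if (n < 2) stop("invalid-input: need at least 2 aligned rows", call. = FALSE)
  chars <- lapply(alignment$rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- .identity_chars(chars[[i]], chars[[j]],
                                            exclude_both_gaps, gap_mismatch,
                                            n_mismatch)
    }
  }
  dimnames(m) <- list(alignment$labels, alignment$labels)
  similarity_matrix(m, "identity")
}
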