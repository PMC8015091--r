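# All-pairs signature comparison: Pearson correlation over the full 4^k
# score vector, assembled into a labeled square similarity matrix.

#' Pearson correlation between two signatures
#'
#' Standard product-moment correlation over all \code{4^k} score entries.
#' Scores are compared whole: no filtering of zero or extreme entries.
#'
#' @param a,b \code{wgks_signature} vectors with the same k.
#' @return correlation in \eqn{[-1, 1]}.
#' @export
signature_pcc <- function(a, b) {
  if (!inherits(a, "wgks_signature") || !inherits(b, "wgks_signature"))
    stop("invalid-input: need two wgks_signature vectors", call. = FALSE)
  if (attr(a, "k") != attr(b, "k"))
    stop("invalid-parameter: signatures have different k", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate-input: signature has zero variance; PCC undefined", call. = FALSE)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Similarity matrix container
#'
#' A square symmetric matrix of pairwise species similarities with unit
#' diagonal: either Pearson correlations between signatures
#' (\code{kind = "pcc"}) or alignment identities (\code{kind = "identity"}).
#'
#' @param values square numeric matrix with identical row/column labels.
#' @param kind \code{"pcc"} or \code{"identity"}.
#' @return the matrix with class \code{similarity_matrix} and attribute
#'   \code{kind}.
#' @export
similarity_matrix <- function(values, kind = c("pcc", "identity")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("invalid-input: similarity matrix must be square", call. = FALSE)
  labels <- rownames(values)
  if (is.null(labels) || !identical(labels, colnames(values)) || anyDuplicated(labels))
    stop("invalid-input: matrix needs matching, unique row/column labels", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12)
    stop("invalid-input: matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(values) - 1)) > 1e-12)
    stop("invalid-input: similarity diagonal must be 1", call. = FALSE)
  lo <- if (kind == "identity") 0 else -1
  if (min(values) < lo - 1e-12 || max(values) > 1 + 1e-12)
    stop("invalid-input: values outside [", lo, ", 1]", call. = FALSE)
  structure(values, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> kind =", attr(x, "kind"), "|", nrow(x), "species\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' All-pairs PCC matrix over species signatures
#'
#' @param signatures list of \code{wgks_signature} objects, all at the same
#'   k, with unique species labels.
#' @return a [similarity_matrix()] of kind \code{"pcc"}; label order follows
#'   the input.
#' @export
pcc_matrix <- function(signatures) {
  if (!is.list(signatures) || length(signatures) < 2)
    stop("invalid-input: need at least two signatures", call. = FALSE)
  ks <- vapply(signatures, function(s) attr(s, "k"), integer(1))
  if (length(unique(ks)) != 1)
    stop("invalid-parameter: signatures have mixed k", call. = FALSE)
  labels <- unname(vapply(signatures, function(s) attr(s, "species"), character(1)))
  if (anyDuplicated(labels))
    stop("invalid-input: duplicate species labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  sds <- vapply(signatures, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("degenerate-input: zero-variance signature(s): ",
         paste(labels[sds == 0], collapse = ", "), call. = FALSE)
  m <- stats::cor(do.call(cbind, lapply(signatures, as.numeric)))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  similarity_matrix(m, "pcc")
}
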