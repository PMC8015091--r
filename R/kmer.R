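# Core of the whole-genome k-mer signature (WGKS) method: observed counts O,
# Markov expected counts E, and the per-word score S = (O - E)/(O + E).

.MAX_K <- 12L  # memory guard: 4^12 words (~16.8M doubles) is the practical ceiling

#' All DNA words of one length in lexicographic order
#'
#' Order is A < C < G < T, from \code{AA...A} to \code{TT...T}; the rank of a
#' word equals its base-4 encoding with A=0, C=1, G=2, T=3.
#'
#' @param k word length (1 to 12).
#' @return character vector of length \code{4^k}.
#' @examples kmer_words(2)
#' @export
kmer_words <- function(k) {
  k <- .check_k(k, min_k = 1L)
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

.check_k <- function(k, min_k = 1L) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != round(k))
    stop("invalid-parameter: k must be a single integer", call. = FALSE)
  k <- as.integer(k)
  if (k < min_k)
    stop("invalid-parameter: k must be >= ", min_k, call. = FALSE)
  if (k > .MAX_K)
    stop("invalid-parameter: k > ", .MAX_K, " exceeds the memory guard (4^k words)",
         call. = FALSE)
  k
}

#' Count overlapping k-mers in a genome
#'
#' Every overlapping window of length \code{k} whose letters are all in
#' \code{{A,C,G,T}} contributes 1 to its word's count. Windows containing
#' \code{N} (or any other letter) are skipped entirely, and windows never span
#' record boundaries. Only the forward strand is counted by default; with
#' \code{canonical = TRUE} each window is counted under the lexicographically
#' smaller of the word and its reverse complement (a documented deviation from
#' the plain single-strand signature).
#'
#' @param genome a [genome_sequence()].
#' @param k word length (>= 1).
#' @param canonical count canonical (strand-symmetrized) k-mers instead of
#'   forward-strand words. Default \code{FALSE}.
#' @return named integer vector of length \code{4^k} (lexicographic word
#'   order), class \code{kmer_counts}, with attributes \code{k} and
#'   \code{species}.
#' @examples
#' count_kmers(genome_sequence("ACGT", "toy"), 2)[c("AC", "CG", "GT")]
#' @export
count_kmers <- function(genome, k, canonical = FALSE) {
  if (!inherits(genome, "genome_sequence"))
    stop("invalid-input: 'genome' must be a genome_sequence", call. = FALSE)
  k <- .check_k(k, min_k = 1L)
  recs <- genome$records[nchar(genome$records) >= k]
  if (length(recs) == 0)
    stop("invalid-input: no record of genome '", genome$species_label,
         "' is at least k = ", k, " bases long", call. = FALSE)
  x <- Biostrings::DNAStringSet(recs)
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = k))
  if (canonical) {
    words <- names(counts)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
    canon <- ifelse(words <= rc, words, rc)
    folded <- rowsum(unname(counts), canon)
    counts[] <- 0
    counts[rownames(folded)] <- folded[, 1]
  }
  structure(as.integer(counts), names = names(counts), k = k,
            species = genome$species_label, class = "kmer_counts")
}

#' Markov expected k-mer counts from shorter-word counts
#'
#' For each word \code{w} of length k, the expected occurrence is
#' \deqn{E(w) = O(w_{1..k-1}) \cdot O(w_{2..k}) / O(w_{2..k-1}),}
#' the product of the prefix and suffix (k-1)-mer counts divided by the count
#' of the central (k-2)-mer. This is the maximal-order Markov prediction of
#' the k-mer count from its sub-word counts; \code{E(w) = 0} whenever the
#' central count is 0.
#'
#' @param o_k1 \code{kmer_counts} at word length \code{k - 1}.
#' @param o_k2 \code{kmer_counts} at word length \code{k - 2}.
#' @param k target word length (>= 3; the central word must be non-empty).
#' @return named numeric vector of length \code{4^k}, class
#'   \code{kmer_expected}, attribute \code{k}.
#' @export
expected_counts <- function(o_k1, o_k2, k) {
  k <- .check_k(k, min_k = 3L)
  if (!inherits(o_k1, "kmer_counts") || !inherits(o_k2, "kmer_counts"))
    stop("invalid-input: count tables must be kmer_counts", call. = FALSE)
  if (attr(o_k1, "k") != k - 1L || attr(o_k2, "k") != k - 2L)
    stop("invalid-parameter: need counts at word lengths k-1 = ", k - 1L,
         " and k-2 = ", k - 2L, call. = FALSE)
  n4 <- 4^k
  r <- seq_len(n4) - 1              # lexicographic rank, base-4 with A=0..T=3
  prefix <- r %/% 4                 # drop last letter  -> (k-1)-mer rank
  suffix <- r %% (4^(k - 1))        # drop first letter -> (k-1)-mer rank
  middle <- suffix %/% 4            # drop first & last -> (k-2)-mer rank
  o1 <- as.numeric(o_k1)
  o2 <- as.numeric(o_k2)
  den <- o2[middle + 1]
  e <- ifelse(den > 0, o1[prefix + 1] * o1[suffix + 1] / den, 0)
  structure(e, names = kmer_words(k), k = k,
            species = attr(o_k1, "species"), class = "kmer_expected")
}

#' Score observed against expected k-mer counts
#'
#' The score of each word is \eqn{S = (O - E)/(O + E)}, in \eqn{[-1, 1]}:
#' S tends to 1 for overrepresented words (O >> E), to -1 for
#' underrepresented words (O << E), and is 0 when O = E (a word occurring at
#' its random expectation). When O and E are both 0 the word is absent and
#' unpredicted, and the score is defined as the neutral value 0.
#'
#' @param observed \code{kmer_counts} at word length k.
#' @param expected \code{kmer_expected} at the same k.
#' @return a \code{wgks_signature}: named numeric vector of length
#'   \code{4^k} in lexicographic word order, attributes \code{k} and
#'   \code{species}.
#' @export
score_signature <- function(observed, expected) {
  if (!inherits(observed, "kmer_counts") || !inherits(expected, "kmer_expected"))
    stop("invalid-input: need kmer_counts and kmer_expected", call. = FALSE)
  if (attr(observed, "k") != attr(expected, "k"))
    stop("invalid-parameter: observed and expected word lengths differ", call. = FALSE)
  o <- as.numeric(observed)
  e <- as.numeric(expected)
  tot <- o + e
  s <- ifelse(tot > 0, (o - e) / tot, 0)
  structure(s, names = names(observed), k = attr(observed, "k"),
            species = attr(observed, "species"), class = "wgks_signature")
}

#' Whole-genome k-mer signature of one genome
#'
#' Runs the full scoring pipeline for one assembly: count all (k-2)-, (k-1)-
#' and k-mers, form the Markov expected counts, and score every word. The
#' result is the genome's signature: \code{4^k} scores in lexicographic word
#' order. The signature is invariant to duplication of the genome (O and E
#' scale together, and the score is scale-free).
#'
#' @param genome a [genome_sequence()].
#' @param k word length, 3 to 12. Default 8 (65,536 octamers), the scale at
#'   which mammalian assemblies were originally compared.
#' @param canonical passed to [count_kmers()].
#' @return a \code{wgks_signature} of length \code{4^k}.
#' @examples
#' s <- wgks_signature(genome_sequence("AAAA", "toy"), k = 3)
#' s[["AAA"]]  # (2 - 2.25) / (2 + 2.25)
#' @export
wgks_signature <- function(genome, k = 8, canonical = FALSE) {
  k <- .check_k(k, min_k = 3L)
  o  <- count_kmers(genome, k, canonical = canonical)
  o1 <- count_kmers(genome, k - 1L, canonical = canonical)
  o2 <- count_kmers(genome, k - 2L, canonical = canonical)
  score_signature(o, expected_counts(o1, o2, k))
}

#' @export
print.wgks_signature <- function(x, ...) {
  cat("<wgks_signature> ", attr(x, "species"), ": k = ", attr(x, "k"),
      ", ", length(x), " words, score range [",
      sprintf("%.3f", min(x)), ", ", sprintf("%.3f", max(x)), "]\n", sep = "")
  invisible(x)
}
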