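# Synthetic data with known ground truth: clade-structured Markov genomes
# (for the signature pipeline) and gapped alignments with a closed-form
# expected identity (for the identity pipeline).

#' Specification of a clade-structured synthetic genome set
#'
#' Describes a two-level hierarchy: one base Markov chain, perturbed once per
#' clade (scale \code{clade_divergence}) and again per species (scale
#' \code{species_divergence}, smaller). Perturbations act on the log scale of
#' the transition probabilities with renormalization, so transition matrices
#' stay valid while clades acquire genuinely different k-mer composition.
#'
#' The chain order bounds the word lengths at which signatures carry
#' heritable signal: the expected-count model predicts k-mer counts exactly
#' for any chain of order <= k-2, so only words with \code{k <= markov_order
#' + 1} retain systematic, clade-specific scores. The default order 5
#' supports signatures up to k = 6.
#'
#' @param n_clades number of clades (>= 2).
#' @param species_per_clade species per clade (>= 2).
#' @param genome_length bases per genome; at least \code{10 * 4^markov_order}
#'   so every transition context is visited.
#' @param markov_order chain order (>= 1). Default 5.
#' @param clade_divergence scale (log-probability sd) of the per-clade
#'   perturbation; > 0. Default 0.5.
#' @param species_divergence scale of the per-species perturbation;
#'   must be < \code{clade_divergence}. Default 0.05.
#' @param seed integer seed; the whole genome set is reproducible from it.
#' @return validated list of class \code{clade_spec}.
#' @export
clade_spec <- function(n_clades = 3, species_per_clade = 4,
                       genome_length = 200000, markov_order = 5,
                       clade_divergence = 0.5, species_divergence = 0.05,
                       seed = 1L) {
  if (n_clades < 2) stop("invalid-parameter: n_clades must be >= 2", call. = FALSE)
  if (species_per_clade < 2)
    stop("invalid-parameter: species_per_clade must be >= 2", call. = FALSE)
  if (markov_order < 1) stop("invalid-parameter: markov_order must be >= 1", call. = FALSE)
  if (clade_divergence <= 0)
    stop("invalid-parameter: clade_divergence must be > 0", call. = FALSE)
  if (species_divergence < 0 || species_divergence >= clade_divergence)
    stop("invalid-parameter: need 0 <= species_divergence < clade_divergence",
         call. = FALSE)
  if (genome_length < 10 * 4^markov_order)
    stop("invalid-parameter: genome_length must be >= 10 * 4^markov_order = ",
         10 * 4^markov_order, call. = FALSE)
  structure(list(n_clades = as.integer(n_clades),
                 species_per_clade = as.integer(species_per_clade),
                 genome_length = as.integer(genome_length),
                 markov_order = as.integer(markov_order),
                 clade_divergence = clade_divergence,
                 species_divergence = species_divergence,
                 seed = as.integer(seed)),
            class = "clade_spec")
}

# Sample n bases (0..3) from an order-m chain given row-wise log-probability
# matrix (4^m contexts x 4). Plain R loop over cumulative probabilities.
.sample_chain <- function(n, m, logp) {
  p <- exp(logp - apply(logp, 1, max))
  p <- p / rowSums(p)
  cp <- t(apply(p, 1, cumsum))
  out <- integer(n)
  out[1:m] <- sample.int(4L, m, replace = TRUE) - 1L
  ctx <- 0L
  for (i in 1:m) ctx <- (ctx * 4L + out[i])
  mod <- as.integer(4^m)
  u <- stats::runif(n)
  for (i in (m + 1):n) {
    row <- cp[ctx + 1L, ]
    r <- u[i]
    b <- if (r < row[1]) 0L else if (r < row[2]) 1L else if (r < row[3]) 2L else 3L
    out[i] <- b
    ctx <- (ctx * 4L + b) %% mod
  }
  out
}

.bases <- c("A", "C", "G", "T")

#' Generate clade-structured synthetic genomes
#'
#' Draws the base/clade/species transition log-probabilities described in
#' [clade_spec()], samples one genome per species, and splits each genome
#' into 2–5 records (so record-boundary handling is exercised). Labels are
#' \code{cladeC_spS}; the planted partition is attached as attribute
#' \code{clade_map}.
#'
#' @param spec a [clade_spec()].
#' @return list of [genome_sequence()] objects with attribute
#'   \code{clade_map} (named integer vector: species label -> clade id).
#' @export
generate_clade_genomes <- function(spec) {
  stopifnot(inherits(spec, "clade_spec"))
  with_seed(spec$seed, {
    m <- spec$markov_order
    ncx <- 4^m
    base <- matrix(stats::rnorm(ncx * 4, 0, 0.3), ncx, 4)
    genomes <- list()
    clade_map <- integer(0)
    for (cl in seq_len(spec$n_clades)) {
      clade_logp <- base + matrix(stats::rnorm(ncx * 4, 0, spec$clade_divergence),
                                  ncx, 4)
      for (sp in seq_len(spec$species_per_clade)) {
        sp_logp <- clade_logp +
          matrix(stats::rnorm(ncx * 4, 0, spec$species_divergence), ncx, 4)
        seq_int <- .sample_chain(spec$genome_length, m, sp_logp)
        n_rec <- sample(2:5, 1)
        cuts <- sort(sample(seq_len(spec$genome_length - 1), n_rec - 1))
        bounds <- c(0, cuts, spec$genome_length)
        recs <- vapply(seq_len(n_rec), function(i) {
          paste(.bases[seq_int[(bounds[i] + 1):bounds[i + 1]] + 1], collapse = "")
        }, character(1))
        label <- sprintf("clade%d_sp%d", cl, sp)
        genomes[[label]] <- genome_sequence(recs, label)
        clade_map[label] <- cl
      }
    }
    attr(genomes, "clade_map") <- clade_map
    genomes
  })
}

#' Generate a gapped alignment with known expected identity
#'
#' An ancestral i.i.d. uniform sequence is copied to each species; each site
#' mutates independently with probability \code{divergence} (to one of the
#' three other bases, uniformly) and is gapped independently with
#' probability \code{gap_rate}. The expected pairwise identity under the
#' default identity dialect is given in closed form by
#' [expected_pairwise_identity()].
#'
#' @param n_species number of rows (>= 2).
#' @param length alignment columns.
#' @param divergence per-site, per-lineage substitution probability in
#'   \eqn{[0, 1)}.
#' @param gap_rate per-site, per-lineage gap probability in \eqn{[0, 0.5)}.
#' @param seed integer seed.
#' @return an [alignment_block()] with labels \code{sp1..spN}.
#' @export
generate_alignment <- function(n_species, length, divergence, gap_rate = 0,
                               seed = 1L) {
  if (n_species < 2) stop("invalid-parameter: n_species must be >= 2", call. = FALSE)
  if (divergence < 0 || divergence >= 1)
    stop("invalid-parameter: divergence must be in [0, 1)", call. = FALSE)
  if (gap_rate < 0 || gap_rate >= 0.5)
    stop("invalid-parameter: gap_rate must be in [0, 0.5)", call. = FALSE)
  with_seed(seed, {
    anc <- sample.int(4L, length, replace = TRUE)
    rows <- vapply(seq_len(n_species), function(s) {
      x <- anc
      mut <- stats::runif(length) < divergence
      if (any(mut)) {
        shift <- sample.int(3L, sum(mut), replace = TRUE)
        x[mut] <- ((x[mut] - 1L + shift) %% 4L) + 1L
      }
      chars <- .bases[x]
      chars[stats::runif(length) < gap_rate] <- "-"
      paste(chars, collapse = "")
    }, character(1))
    alignment_block(rows, sprintf("sp%d", seq_len(n_species)))
  })
}

#' Closed-form expected pairwise identity of the alignment generator
#'
#' Two rows of [generate_alignment()] mutate and gap independently from the
#' same ancestor. Under the default identity dialect (both-gap columns
#' excluded, gap-vs-letter a mismatch), a column is counted unless both rows
#' are gapped (probability \eqn{g^2}) and matches only when both rows carry
#' letters (probability \eqn{(1-g)^2}) that are equal: neither mutated, or
#' both mutated to the same base, \eqn{(1-d)^2 + d^2/3}. Hence
#' \deqn{E[\mathrm{identity}] = \frac{(1-g)^2\,\left[(1-d)^2 + d^2/3\right]}{1 - g^2}.}
#'
#' @param divergence per-lineage substitution probability d.
#' @param gap_rate per-lineage gap probability g.
#' @return expected identity fraction.
#' @export
expected_pairwise_identity <- function(divergence, gap_rate = 0) {
  p_eq <- (1 - divergence)^2 + divergence^2 / 3
  (1 - gap_rate)^2 * p_eq / (1 - gap_rate^2)
}
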