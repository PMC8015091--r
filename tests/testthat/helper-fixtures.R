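# Shared fixtures and independent oracles for the test suite.

# Independent counting oracle: compare the substring at every offset of every
# record against the word list. No rolling encoding, no Biostrings.
naive_count_kmers <- function(records, k) {
  words <- wgks::kmer_words(k)
  counts <- stats::setNames(integer(length(words)), words)
  for (rec in toupper(records)) {
    n <- nchar(rec)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(rec, i, i + k - 1)
      if (!is.na(match(w, words))) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

random_dna <- function(n, seed, n_prob = 0) {
  set.seed(seed)
  alph <- c("A", "C", "G", "T")
  x <- sample(alph, n, replace = TRUE)
  if (n_prob > 0) x[runif(n) < n_prob] <- "N"
  paste(x, collapse = "")
}

# Construct count/expected/signature objects directly for white-box score tests.
make_counts <- function(values, k, species = "x") {
  structure(as.integer(values), names = wgks::kmer_words(k), k = as.integer(k),
            species = species, class = "kmer_counts")
}
make_expected <- function(values, k, species = "x") {
  structure(as.numeric(values), names = wgks::kmer_words(k), k = as.integer(k),
            species = species, class = "kmer_expected")
}
make_sig <- function(values, k, species = "x") {
  structure(as.numeric(values), names = wgks::kmer_words(k), k = as.integer(k),
            species = species, class = "wgks_signature")
}

# Planted three-clade genome set at the generator's study conditions
# (3 clades x 4 species, 200 kb, divergences 0.5/0.05, seed 42), signatures
# at k = 6. Computed once and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

planted_fixture <- function() {
  if (!is.null(.fixture_cache$planted)) return(.fixture_cache$planted)
  spec <- wgks::clade_spec(n_clades = 3, species_per_clade = 4,
                           genome_length = 200000, clade_divergence = 0.5,
                           species_divergence = 0.05, seed = 42)
  genomes <- wgks::generate_clade_genomes(spec)
  sigs <- lapply(genomes, wgks::wgks_signature, k = 6)
  pcc <- wgks::pcc_matrix(sigs)
  .fixture_cache$planted <- list(spec = spec, genomes = genomes,
                                 signatures = sigs, pcc = pcc,
                                 clade_map = attr(genomes, "clade_map"))
  .fixture_cache$planted
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Strip similarity_matrix class/attributes for plain-matrix comparisons.
as_plain <- function(m) {
  m <- unclass(m)
  attr(m, "kind") <- NULL
  m
}
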