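# Readers, writers and the two end-to-end pipelines (signature analysis of
# genome FASTA files; identity analysis of an aligned FASTA).

#' Read a genome assembly from FASTA
#'
#' Multi-record FASTA, plain or gzip-compressed; lowercase and CRLF input
#' are normalized. Record descriptions beyond the identifier are ignored.
#'
#' @param path FASTA file (optionally \code{.gz}).
#' @param species_label label for the assembly; default: file name without
#'   extensions.
#' @return a [genome_sequence()].
#' @export
read_genome_fasta <- function(path, species_label = NULL) {
  recs <- .read_fasta_records(path)
  if (is.null(species_label))
    species_label <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  genome_sequence(unname(recs), species_label)
}

#' Read a multiple alignment from aligned FASTA
#'
#' @param path aligned FASTA file (optionally \code{.gz}); all rows must
#'   have equal length.
#' @return an [alignment_block()] labeled by the FASTA identifiers (first
#'   whitespace-delimited token of each header).
#' @export
read_alignment_fasta <- function(path) {
  rows <- .read_fasta_records(path)
  labels <- sub("\\s.*$", "", names(rows))
  w <- nchar(rows)
  if (length(unique(w)) != 1)
    stop("invalid-input: ", path, ": alignment rows have unequal lengths (",
         paste(range(w), collapse = "-"), "); record(s) ",
         paste(which(w != w[1]), collapse = ","), call. = FALSE)
  alignment_block(unname(rows), labels)
}

.read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("invalid-input: file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("invalid-input: ", path,
                                         ": FASTA parse failed: ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0) stop("invalid-input: ", path, ": no FASTA records", call. = FALSE)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a signature as a two-column TSV (word, score)
#' @param signature a \code{wgks_signature}.
#' @param path output file.
#' @export
write_signature_tsv <- function(signature, path) {
  stopifnot(inherits(signature, "wgks_signature"))
  utils::write.table(
    data.frame(word = names(signature), score = as.numeric(signature)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labeled similarity matrix as TSV
#' @param matrix a [similarity_matrix()].
#' @param path output file.
#' @export
write_similarity_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  m <- unclass(matrix)
  utils::write.table(data.frame(species = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_tsv()]
#' @param path TSV file.
#' @param kind \code{"pcc"} or \code{"identity"}.
#' @return a [similarity_matrix()].
#' @export
read_similarity_tsv <- function(path, kind = "pcc") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- (m + t(m)) / 2  # absorb printed-precision asymmetry
  diag(m) <- 1
  similarity_matrix(m, kind)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of both pipelines in one validated
#' object.
#'
#' @param k signature word length, 3–12 (default 8).
#' @param linkage linkage for cluster extraction: \code{"ward"} (signature
#'   analysis default), \code{"single"} (identity analysis default),
#'   \code{"average"}, or \code{"complete"}.
#' @param n_clusters number of clusters to extract; \code{NULL} picks the
#'   silhouette-maximizing count from the sweep.
#' @param silhouette_range integer vector of length 2: cluster counts swept
#'   (default 2–7, capped at n-1).
#' @param p_test \code{"welch_t"} or \code{"mann_whitney"}.
#' @param hopkins_fraction,hopkins_seed Hopkins subsample fraction and seed.
#' @param canonical count canonical (strand-folded) k-mers.
#' @param exclude_both_gaps,gap_mismatch,n_mismatch identity dialect, see
#'   [identity_pair()].
#' @param out_dir directory for output artifacts; \code{NULL} writes
#'   nothing.
#' @return list of class \code{wgks_config}.
#' @export
wgks_config <- function(k = 8, linkage = "ward", n_clusters = NULL,
                        silhouette_range = c(2, 7), p_test = "welch_t",
                        hopkins_fraction = 0.1, hopkins_seed = 1L,
                        canonical = FALSE,
                        exclude_both_gaps = TRUE, gap_mismatch = TRUE,
                        n_mismatch = TRUE, out_dir = NULL) {
  k <- .check_k(k, min_k = 3L)
  linkage <- match.arg(linkage, c("ward", "single", "average", "complete"))
  p_test <- match.arg(p_test, c("welch_t", "mann_whitney"))
  if (length(silhouette_range) != 2 || silhouette_range[1] < 2 ||
      silhouette_range[1] > silhouette_range[2])
    stop("invalid-parameter: silhouette_range must be c(lo, hi), lo >= 2", call. = FALSE)
  if (!is.null(n_clusters) && n_clusters < 1)
    stop("invalid-parameter: n_clusters must be >= 1", call. = FALSE)
  structure(list(k = k, linkage = linkage, n_clusters = n_clusters,
                 silhouette_range = as.integer(silhouette_range),
                 p_test = p_test, hopkins_fraction = hopkins_fraction,
                 hopkins_seed = as.integer(hopkins_seed),
                 canonical = isTRUE(canonical),
                 exclude_both_gaps = isTRUE(exclude_both_gaps),
                 gap_mismatch = isTRUE(gap_mismatch),
                 n_mismatch = isTRUE(n_mismatch), out_dir = out_dir),
            class = "wgks_config")
}

.as_genomes <- function(genomes) {
  if (is.character(genomes)) genomes <- lapply(genomes, read_genome_fasta)
  if (!is.list(genomes) || !all(vapply(genomes, inherits, logical(1), "genome_sequence")))
    stop("invalid-input: genomes must be FASTA paths or genome_sequence objects",
         call. = FALSE)
  genomes
}

# Shared clustering/diagnostics/tree tail of both pipelines.
.cluster_stage <- function(sim, config) {
  n <- nrow(sim)
  k_max <- min(config$silhouette_range[2], n - 1L)
  sweep <- silhouette_sweep(sim, k_min = config$silhouette_range[1],
                            k_max = k_max, linkage = config$linkage)
  n_clusters <- if (is.null(config$n_clusters)) attr(sweep, "best_k")
                else config$n_clusters
  membership <- cut_clusters(sim, n_clusters, linkage = config$linkage)
  table <- cluster_table(sim, membership, test = config$p_test)
  diagnostics <- list(
    hopkins = hopkins_statistic(sim, config$hopkins_fraction, config$hopkins_seed),
    silhouette = sweep,
    n_clusters = n_clusters,
    linkage = config$linkage,
    p_test = config$p_test)
  list(diagnostics = diagnostics, membership = membership, table = table)
}

.write_common <- function(out_dir, prefix, sim, stage, trees) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_similarity_tsv(sim, file.path(out_dir, paste0(prefix, "_matrix.tsv")))
  tab <- stage$table
  tab$members <- vapply(attr(tab, "members"), paste, character(1), collapse = ",")
  utils::write.table(tab, file.path(out_dir, paste0(prefix, "_clusters.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  diag <- stage$diagnostics
  diag$silhouette <- as.list(diag$silhouette[c("k", "avg_silhouette", "wss")])
  jsonlite::write_json(diag, file.path(out_dir, paste0(prefix, "_diagnostics.json")),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(trees))
    write_newick(trees[[nm]], path = file.path(out_dir, paste0(prefix, "_", nm, ".nwk")))
  invisible(NULL)
}

#' Run the whole-genome signature pipeline
#'
#' genomes -> k-mer score signatures -> all-pairs PCC matrix -> diagnostics
#' (Hopkins, silhouette/elbow sweep) -> cluster extraction with per-cluster
#' statistics and p-values -> UPGMA tree. Deterministic given the inputs and
#' configuration; when \code{config$out_dir} is set, the matrix, cluster
#' table, diagnostics JSON, Newick tree and per-species signature TSVs are
#' written there.
#'
#' @param genomes list of [genome_sequence()] objects, or character vector
#'   of FASTA paths.
#' @param config a [wgks_config()]; default uses k = 8 and Ward linkage.
#' @return list with \code{signatures}, \code{pcc} (similarity_matrix),
#'   \code{diagnostics}, \code{membership}, \code{cluster_table},
#'   \code{tree} (UPGMA phylo).
#' @export
run_wgks_pipeline <- function(genomes, config = wgks_config()) {
  stopifnot(inherits(config, "wgks_config"))
  genomes <- .as_genomes(genomes)
  if (length(genomes) < 2)
    stop("wgks-pipeline: need at least two genomes", call. = FALSE)
  signatures <- tryCatch(
    lapply(genomes, wgks_signature, k = config$k, canonical = config$canonical),
    error = function(e) stop("wgks-pipeline[signature]: ", conditionMessage(e),
                             call. = FALSE))
  sim <- tryCatch(pcc_matrix(signatures),
                  error = function(e) stop("wgks-pipeline[pcc]: ",
                                           conditionMessage(e), call. = FALSE))
  stage <- tryCatch(.cluster_stage(sim, config),
                    error = function(e) stop("wgks-pipeline[cluster]: ",
                                             conditionMessage(e), call. = FALSE))
  tree <- upgma_tree(sim)
  if (!is.null(config$out_dir)) {
    .write_common(config$out_dir, "wgks", sim, stage, list(upgma = tree))
    for (s in signatures)
      write_signature_tsv(s, file.path(config$out_dir,
                                       paste0("signature_", attr(s, "species"), ".tsv")))
  }
  list(signatures = signatures, pcc = sim, diagnostics = stage$diagnostics,
       membership = stage$membership, cluster_table = stage$table, tree = tree)
}

#' Run the alignment-identity pipeline
#'
#' aligned FASTA -> pairwise sequence-identity matrix -> diagnostics ->
#' cluster extraction with statistics and p-values -> UPGMA and
#' neighbor-joining trees. Mirrors the mitochondrial-genome analysis route;
#' single linkage is the conventional choice there.
#'
#' @param alignment an [alignment_block()] or path to an aligned FASTA.
#' @param config a [wgks_config()]; \code{linkage = "single"} by default.
#' @return list with \code{identity} (similarity_matrix),
#'   \code{diagnostics}, \code{membership}, \code{cluster_table},
#'   \code{upgma}, \code{nj} (phylo trees).
#' @export
run_identity_pipeline <- function(alignment,
                                  config = wgks_config(linkage = "single")) {
  stopifnot(inherits(config, "wgks_config"))
  if (is.character(alignment)) alignment <- read_alignment_fasta(alignment)
  stopifnot(inherits(alignment, "alignment_block"))
  sim <- tryCatch(
    identity_matrix(alignment, config$exclude_both_gaps, config$gap_mismatch,
                    config$n_mismatch),
    error = function(e) stop("identity-pipeline[matrix]: ",
                             conditionMessage(e), call. = FALSE))
  if (all(abs(unclass(sim)[upper.tri(sim)] - 1) < 1e-12))
    stop("identity-pipeline[cluster]: degenerate-input: all sequences identical; ",
         "no clustering structure to extract", call. = FALSE)
  stage <- tryCatch(.cluster_stage(sim, config),
                    error = function(e) stop("identity-pipeline[cluster]: ",
                                             conditionMessage(e), call. = FALSE))
  upgma <- upgma_tree(sim)
  nj <- if (nrow(sim) >= 3) nj_tree(sim) else NULL
  if (!is.null(config$out_dir)) {
    trees <- list(upgma = upgma)
    if (!is.null(nj)) trees$nj <- nj
    .write_common(config$out_dir, "identity", sim, stage, trees)
  }
  list(identity = sim, diagnostics = stage$diagnostics,
       membership = stage$membership, cluster_table = stage$table,
       upgma = upgma, nj = nj)
}
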