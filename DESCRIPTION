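Package: wgks
Title: Whole-Genome K-mer Signature Analysis for Alignment-Free Species Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free comparison of genome assemblies through whole-genome
    k-mer signatures. Every k-mer's observed occurrence is scored against a
    Markov-style expected occurrence derived from its two (k-1)-mer counts and
    its central (k-2)-mer count, giving a score vector in [-1, 1] over all 4^k
    words that is invariant to genome duplication. Signatures are compared with
    Pearson correlation to build an all-pairs similarity matrix, which feeds
    clustering-tendency diagnostics (Hopkins statistic, silhouette sweeps),
    hierarchical cluster extraction with per-cluster similarity statistics and
    p-values, and UPGMA / neighbor-joining trees serialized to Newick. A
    parallel stage computes pairwise sequence-identity matrices from multiple
    alignments (for mitochondrial genome data) and reuses the same clustering
    and tree machinery. A synthetic generator produces clade-structured Markov
    genomes and gapped alignments with known ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
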