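---
title: "Whole-genome k-mer signatures: model, diagnostics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome k-mer signatures: model, diagnostics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgks)
```

## The signature model

`wgks` compares genome assemblies without alignment. Each genome is reduced
to a *whole-genome k-mer signature*: a vector of `4^k` scores, one per DNA
word of length k in lexicographic order (`AA…A` to `TT…T`). For each word
`w` the observed occurrence `O(w)` — the number of overlapping windows of
the genome spelling `w` — is compared against a Markov-style expectation
built from the genome's own shorter-word counts:

$$E(w) \;=\; \frac{O(w_{1..k-1}) \cdot O(w_{2..k})}{O(w_{2..k-1})},$$

the product of the prefix and suffix (k−1)-mer counts divided by the count
of the central (k−2)-mer, with `E = 0` when the central count is 0. The
score is the symmetric relative deviation

$$S(w) \;=\; \frac{O(w) - E(w)}{O(w) + E(w)} \in [-1, 1],$$

which tends to 1 for overrepresented words, −1 for underrepresented words,
and is 0 at `O = E`. Because `O` and `E` scale together, the signature is
invariant to partial or complete duplication of the genome — a property the
test suite checks to `1e-12`. Species are then compared by the Pearson
correlation (PCC) of their full score vectors, over all `4^k` entries with
no filtering, giving a square similarity matrix that drives clustering and
tree building.

The signal in `S` is precisely the part of k-mer composition that shorter
words cannot explain: `E` is the maximal-order Markov prediction from
(k−1)-mer counts, so any sequence whose dependence structure has order
≤ k−2 scores near zero everywhere. In real genomes the deviations are
dominated by repeat families, binding-site cores and other long-range
word preferences, which are heritable and therefore similar between
related species.

### Tunable parameters

* `k` (default **8**, configurable 3–12): word length. `k = 8` gives
  65,536 octamer scores, a scale at which mammalian assemblies have on the
  order of tens of thousands of occurrences per word; larger k raises
  resolution but quickly dilutes counts (and memory: the package refuses
  k > 12). Small genomes and the package's own simulations use k = 4–6.
* `canonical` (default `FALSE`): fold each word with its reverse
  complement before scoring. The plain signature is single-stranded; the
  canonical mode is offered for strand-symmetric comparisons and is a
  documented deviation from the plain definition.
* Windows containing any letter outside `A,C,G,T` (assembly `N` runs in
  particular) are skipped entirely, and windows never span record
  boundaries — concatenating scaffolds would manufacture chimeric words
  and would also break exact duplication invariance.
* The `O = 0, E = 0` case (word absent and unpredicted) is scored 0, the
  only finite choice symmetric between over- and underrepresentation.

## Clustering layer

Distances are `d = 1 − similarity` throughout: the simplest monotone
transform, applied identically to PCC and identity matrices.

* **Hopkins statistic** (`hopkins_statistic`): each matrix row is treated
  as a point in $R^n$; a subsample (fraction 0.1, at least 3 points) is
  compared against uniform reference points drawn from the per-dimension
  bounding box, and $H = \sum u / (\sum u + \sum w)$ with `u` the
  reference-to-data and `w` the data-to-data nearest-neighbour distances.
  H ≈ 0.5 indicates no clustering tendency; values near 1 indicate strong
  structure. The subsample seed defaults to 1 and is a parameter, so the
  diagnostic is reproducible.
* **Silhouette sweep** (`silhouette_sweep`): the hierarchical tree is cut
  into k = 2…7 clusters (capped at n−1) and the average silhouette width
  is reported per k, together with the total within-cluster sum of squared
  distances (the "wss" elbow curve). The silhouette-maximizing k is the
  default cluster count of the pipelines.
* **Cluster extraction** (`cut_clusters`): agglomerative clustering with
  Ward linkage (`ward.D`) by default for signature matrices and single
  linkage for identity matrices, cut with `cutree`; k-means and PAM are
  available as alternative extractors but are not on the primary path.
* **Per-cluster statistics** (`cluster_table`): for each cluster, the
  min/mean/max/standard deviation of within-cluster pairwise similarities
  and a one-sided p-value testing that within-cluster pairs are more
  similar than mixed pairs (one member, one outsider). The default test is
  a one-sided Welch two-sample t-test; with hundreds of pairs this is what
  produces the astronomically small p-values typical of clean clade
  structure. A Mann–Whitney option guards against non-normality. Edge
  cases are explicit: a 2-species cluster (one within pair) degenerates to
  a one-sample t-test of the mixed pairs against that value and reports no
  standard deviation; a singleton reports all statistics as missing; if
  the similarities are essentially constant the t statistic is undefined
  and the rank test is used instead. Under an exchangeable null the
  p-values are approximately uniform, which the suite checks with a
  Kolmogorov–Smirnov test over 200 simulated matrices.

## Trees

`upgma_tree` is average-linkage agglomeration (via `hclust`), producing an
ultrametric tree with each merge at height h placing leaves at depth h/2;
`nj_tree` is classic Saitou–Nei neighbor joining (via `ape::nj`), which
recovers additive distance matrices exactly. Negative NJ branches — an
artifact on non-additive input — are clamped to zero with the negative
amount transferred to the sister branch, preserving path lengths through
the parent node. Newick serialization quotes labels containing reserved
characters (doubling embedded quotes) and round-trips through the
package's own reader; both facts are property-tested on random trees.
Maximum-likelihood trees and bootstrap support are out of scope: they
operate on aligned sequences, not on the similarity matrices this package
produces.

## Identity stage

For curated sets such as complete mitochondrial genomes, a supplied
multiple alignment replaces the signature: `identity_matrix` scores each
pair of rows by the fraction of identical counted columns. Alignment
identity tools differ silently in their gap conventions, so the dialect
here is explicit and switchable: both-gap columns are excluded from the
denominator, a gap against a letter is a mismatch, and `N` matches nothing
(even another `N`). The same clustering and tree machinery then applies,
conventionally with single linkage.

## What the synthetic generator emulates — and what it does not

`generate_clade_genomes` plants a known two-level structure: one base
Markov transition matrix, perturbed once per clade (log-probability noise
of scale `clade_divergence`, default 0.5) and again per species (scale
`species_divergence`, default 0.05), then sampled into genomes split into
2–5 records. The defaults — 3 clades × 4 species, 200 kb genomes,
divergences 0.5/0.05 — are the package's standard simulation conditions:
large enough that within-clade PCC (~0.9) separates cleanly from
between-clade PCC (~0.2), small enough that the full pipeline runs in
seconds.

The chain order defaults to **5**. This is a consequence of the score
model, not a free choice: the expectation `E` absorbs all dependence of
order ≤ k−2, so a chain of order m only leaves systematic signal in
signatures with k ≤ m+1. At the simulation word length k = 6 an order-2
chain yields signatures that are pure sampling noise (measured within- and
between-clade PCC both ≈ 0.01), whereas order 5 leaves clade-specific
structure at exactly the margin the model can see. The generator
validates `genome_length ≥ 10·4^order` so every transition context is
visited.

What this emulates is the *statistical* premise of the method — heritable
word preferences shared within groups. What it does not emulate: repeat
families (the dominant driver of real signatures), GC isochores, coding
structure, indels, or any evolutionary process on a tree (clades here are
star-shaped perturbations). Passing the planted-clade tests therefore
demonstrates that the pipeline recovers group structure when the model's
assumptions hold; it does not validate the biological interpretation of
clusters on real assemblies.

`generate_alignment` mutates an ancestral i.i.d. sequence independently
per lineage (per-site substitution probability d, gap probability g),
giving the closed-form expected pairwise identity
$(1-g)^2\,[(1-d)^2 + d^2/3]\,/\,(1-g^2)$ under the default dialect —
the benchmark the identity stage is tested against. Note that because both
lineages mutate, identity at divergence d is approximately $(1-d)^2$, not
$1-d$.

## Numerical and determinism notes

* Counting is exact integer arithmetic (Biostrings); scores and
  correlations are double precision over the full vector.
* All stochastic components (generators, Hopkins subsampling, k-means
  starts) take explicit seeds and restore the caller's RNG state; the
  pipelines are bytewise deterministic given inputs and configuration,
  which the suite asserts by re-running and comparing artifacts.
* Hierarchical merges use `hclust`'s fixed tie-breaking, so permuting the
  input species permutes labels without changing topology.
* Simulation sizes in the test suite (200 kb genomes at k = 6, 5 kb
  alignments, 50-seed diagnostic loops) were chosen as the smallest scales
  at which the asserted properties hold with wide margins; they keep the
  default test run under a minute.

## Known limitations

* The signature compares composition, not homology: it is a
  classification aid, not a substitution-model phylogeny. Branch lengths
  of the UPGMA/NJ trees are correlation distances, not substitutions per
  site.
* Very small or highly fragmented assemblies dilute counts at k = 8;
  choose k so that `4^k` is well below the genome length.
* The cluster p-values treat species pairs as exchangeable observations;
  pairs sharing a species are not independent, so the p-values are
  comparative evidence, not literal error rates (their null calibration is
  checked empirically).
* `identity_matrix` is quadratic in the number of sequences and linear in
  alignment length; it is intended for dozens of organelle genomes, not
  thousands of sequences.
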