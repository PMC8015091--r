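# Internal helpers.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Map a linkage name to the stats::hclust method string. "ward" means the
# original Ward criterion on the similarity-derived distances ("ward.D").
.linkage_method <- function(linkage) {
  switch(match.arg(linkage, c("average", "ward", "single", "complete")),
         average = "average", ward = "ward.D", single = "single",
         complete = "complete")
}

# Distance object from a similarity matrix: d = 1 - similarity.
.sim_to_dist <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  stats::as.dist(1 - unclass(m))
}
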