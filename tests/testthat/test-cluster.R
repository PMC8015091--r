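# Helper: block similarity matrix with given within/between values.
block_matrix <- function(sizes, within = 0.95, between = 0.2, jitter = 0,
                         seed = 1) {
  n <- sum(sizes)
  lab <- paste0("sp", seq_len(n))
  grp <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n, dimnames = list(lab, lab))
  for (g in seq_along(sizes)) m[grp == g, grp == g] <- within
  if (jitter > 0) {
    set.seed(seed)
    noise <- matrix(runif(n * n, -jitter, jitter), n, n)
    noise <- (noise + t(noise)) / 2
    m <- pmin(pmax(m + noise, -1), 1)
  }
  diag(m) <- 1
  list(matrix = similarity_matrix(m, "pcc"), groups = setNames(grp, lab))
}

test_that("Hopkins statistic separates uniform from clustered point sets", {
  set.seed(77)
  blobs <- rbind(matrix(rnorm(40 * 4, 0, 0.05), 40, 4),
                 matrix(rnorm(40 * 4, 3, 0.05), 40, 4))
  expect_gt(hopkins_statistic(blobs, 0.1, seed = 3), 0.8)

  unif <- matrix(runif(200 * 3), 200, 3)
  h <- hopkins_statistic(unif, 0.1, seed = 3)
  expect_gt(h, 0)
  expect_lt(h, 1)
  # reproducible given the seed, different under another seed's subsample
  expect_identical(h, hopkins_statistic(unif, 0.1, seed = 3))

  bm <- block_matrix(c(5, 5), jitter = 0.02)
  expect_gt(hopkins_statistic(bm$matrix, 0.25, seed = 1), 0.7)

  expect_error(hopkins_statistic(unif[1:3, ]), "at least 4")
  expect_error(hopkins_statistic(unif, 0.9), "sample_fraction")
})

test_that("silhouette sweep finds ideal separation and valid ranges", {
  bm <- block_matrix(c(4, 4), within = 1, between = 0)
  sweep <- silhouette_sweep(bm$matrix, 2, 5, linkage = "average")
  expect_equal(sweep$avg_silhouette[sweep$k == 2], 1)
  expect_equal(attr(sweep, "best_k"), 2L)
  expect_true(all(sweep$avg_silhouette >= -1 & sweep$avg_silhouette <= 1))
  expect_true(all(diff(sweep$wss) <= 1e-12))  # wss non-increasing in k here

  expect_error(silhouette_sweep(bm$matrix, 2, 8), "k_max")
  expect_error(silhouette_sweep(bm$matrix, 1, 3), "k_min")
})

test_that("cutting the tree yields exact partitions at the extremes", {
  bm <- block_matrix(c(3, 4, 5), jitter = 0.03)
  n <- nrow(bm$matrix)
  singletons <- cut_clusters(bm$matrix, n)
  expect_equal(length(unique(singletons)), n)
  one <- cut_clusters(bm$matrix, 1)
  expect_equal(unname(unique(one)), 1L)

  memb <- cut_clusters(bm$matrix, 3, linkage = "average")
  # a partition: every species in exactly one cluster
  expect_setequal(names(memb), rownames(bm$matrix))
  expect_equal(adjusted_rand(memb, bm$groups), 1)

  expect_error(cut_clusters(bm$matrix, 0), "invalid-parameter")
  expect_error(cut_clusters(bm$matrix, n + 1), "invalid-parameter")
})

test_that("cluster statistics summarize within pairs and order correctly", {
  bm <- block_matrix(c(5, 5), within = 1, between = 0)
  rep1 <- cluster_pvalue(bm$matrix, paste0("sp", 1:5))
  expect_lt(rep1$p_value, 0.001)
  expect_equal(rep1$n_species, 5)
  expect_equal(c(rep1$min, rep1$mean, rep1$max), c(1, 1, 1))

  bm2 <- block_matrix(c(4, 4, 2), jitter = 0.05, seed = 11)
  tab <- cluster_table(bm2$matrix, bm2$groups)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("cluster", "n_species", "min", "mean", "max", "stdev",
                      "p_value"))
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  # stdev is NA for the 2-species cluster, defined for the 4-species ones
  expect_true(is.na(tab$stdev[tab$n_species == 2]))
  expect_true(all(!is.na(tab$stdev[tab$n_species >= 3])))

  # singleton: no within pairs, everything missing
  memb <- setNames(c(1, rep(2, 9)), rownames(bm$matrix))
  tab2 <- cluster_table(bm$matrix, memb)
  expect_true(is.na(tab2$p_value[tab2$n_species == 1]))
  expect_true(is.na(tab2$min[tab2$n_species == 1]))

  # Mann-Whitney variant stays in range
  tabw <- cluster_table(bm2$matrix, bm2$groups, test = "mann_whitney")
  expect_true(all(tabw$p_value > 0 & tabw$p_value <= 1))

  expect_error(cluster_pvalue(bm$matrix, rownames(bm$matrix)), "proper subset")
  expect_error(cluster_pvalue(bm$matrix, "nope"), "labels")
})

test_that("cluster p-values are calibrated under exchangeable similarities", {
  n <- 16
  lab <- paste0("s", seq_len(n))
  pvals <- vapply(seq_len(200), function(s) {
    set.seed(4000 + s)
    m <- matrix(0, n, n, dimnames = list(lab, lab))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    diag(m) <- 1
    sm <- similarity_matrix(m, "identity")
    cluster_pvalue(sm, lab[1:8])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("k-means and PAM extractors recover clean partitions too", {
  bm <- block_matrix(c(5, 5, 5), jitter = 0.02, seed = 8)
  for (method in c("kmeans", "pam")) {
    memb <- partition_clusters(bm$matrix, 3, method = method, seed = 2)
    expect_equal(adjusted_rand(memb, bm$groups), 1)
  }
})

test_that("planted three-clade genomes maximize the silhouette at k = 3", {
  fx <- planted_fixture()
  sweep <- silhouette_sweep(fx$pcc, 2, 7, linkage = "ward")
  expect_equal(attr(sweep, "best_k"), 3L)
})
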