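# Clustering layer: tendency diagnostics (Hopkins statistic, silhouette and
# elbow sweeps), cluster extraction from hierarchical trees, and per-cluster
# similarity statistics with a within-vs-between p-value.

#' Hopkins clustering-tendency statistic
#'
#' Measures whether a point set is clusterable. A random subsample of the
#' real points is compared with uniform reference points drawn from the
#' per-dimension bounding box of the data: with \eqn{u_j} the nearest-real
#' distance of reference point j and \eqn{w_j} the nearest-other-real
#' distance of sampled real point j, \deqn{H = \sum u_j / (\sum u_j + \sum w_j).}
#' H is near 0.5 for spatially uniform data and approaches 1 for strongly
#' clustered data.
#'
#' @param x a [similarity_matrix()] (each row is treated as a point in
#'   \eqn{R^n}) or a plain numeric matrix of points (rows = observations).
#' @param sample_fraction fraction of points sampled (at least 3 points).
#' @param seed RNG seed for the subsample and reference draw.
#' @return H in (0, 1).
#' @export
hopkins_statistic <- function(x, sample_fraction = 0.1, seed = 1L) {
  pts <- if (inherits(x, "similarity_matrix")) unclass(x) else x
  if (!is.matrix(pts) || !is.numeric(pts))
    stop("invalid-input: x must be a numeric matrix or similarity_matrix", call. = FALSE)
  n <- nrow(pts)
  if (n < 4) stop("invalid-input: need at least 4 rows", call. = FALSE)
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 || sample_fraction > 0.5)
    stop("invalid-parameter: sample_fraction must be in (0, 0.5]", call. = FALSE)
  m <- max(3L, ceiling(sample_fraction * n))
  m <- min(m, n - 1L)  # leave at least one other real point for w
  with_seed(seed, {
    idx <- sample.int(n, m)
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    ref <- vapply(seq_len(ncol(pts)),
                  function(j) stats::runif(m, lo[j], hi[j]), numeric(m))
    ref <- matrix(ref, nrow = m)
    nearest <- function(p, B) sqrt(min(colSums((t(B) - p)^2)))
    u <- vapply(seq_len(m), function(i) nearest(ref[i, ], pts), numeric(1))
    w <- vapply(seq_len(m),
                function(i) nearest(pts[idx[i], ], pts[-idx[i], , drop = FALSE]),
                numeric(1))
    sum(u) / (sum(u) + sum(w))
  })
}

#' Silhouette and elbow sweep over cluster counts
#'
#' Cuts the hierarchical tree of \code{d = 1 - similarity} into k clusters for
#' each k in \code{[k_min, k_max]} and reports the average silhouette width
#' and the total within-cluster sum of squared distances (the "wss" elbow
#' curve). The k maximizing the average silhouette width is the suggested
#' number of clusters.
#'
#' @param matrix a [similarity_matrix()].
#' @param k_min,k_max cluster-count range; \code{2 <= k_min <= k_max < n}.
#' @param linkage \code{"average"}, \code{"ward"}, \code{"single"} or
#'   \code{"complete"}.
#' @return data.frame with columns \code{k}, \code{avg_silhouette},
#'   \code{wss}; attribute \code{best_k}.
#' @export
silhouette_sweep <- function(matrix, k_min = 2, k_max = 7, linkage = "average") {
  stopifnot(inherits(matrix, "similarity_matrix"))
  n <- nrow(matrix)
  if (k_min < 2 || k_min > k_max) stop("invalid-parameter: need 2 <= k_min <= k_max", call. = FALSE)
  if (k_max >= n) stop("invalid-parameter: k_max must be < number of species", call. = FALSE)
  d <- .sim_to_dist(matrix)
  dm <- as.matrix(d)
  hc <- stats::hclust(d, method = .linkage_method(linkage))
  ks <- k_min:k_max
  res <- lapply(ks, function(k) {
    memb <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(memb, d)
    wss <- sum(vapply(split(names(memb), memb), function(members) {
      sub <- dm[members, members, drop = FALSE]
      sum(sub^2) / (2 * length(members))
    }, numeric(1)))
    c(avg_silhouette = mean(sil[, "sil_width"]), wss = wss)
  })
  out <- data.frame(k = ks, do.call(rbind, res))
  attr(out, "best_k") <- ks[which.max(out$avg_silhouette)]
  out
}

#' Extract clusters by cutting a hierarchical tree
#'
#' Agglomerative clustering of \code{d = 1 - similarity} with the chosen
#' linkage, cut into exactly \code{n_clusters} groups. Deterministic: ties
#' are resolved by \code{stats::hclust}'s fixed ordering.
#'
#' @inheritParams silhouette_sweep
#' @param n_clusters number of clusters, \code{1 <= n_clusters <= n}.
#' @return named integer vector mapping each species label to a cluster id
#'   (1-based, in order of first appearance down the tree cut).
#' @export
cut_clusters <- function(matrix, n_clusters, linkage = "average") {
  stopifnot(inherits(matrix, "similarity_matrix"))
  n <- nrow(matrix)
  if (!is.numeric(n_clusters) || n_clusters < 1 || n_clusters > n)
    stop("invalid-parameter: n_clusters must be in [1, ", n, "]", call. = FALSE)
  if (n_clusters == n) {
    memb <- seq_len(n)
    names(memb) <- rownames(matrix)
    return(memb)
  }
  hc <- stats::hclust(.sim_to_dist(matrix), method = .linkage_method(linkage))
  stats::cutree(hc, k = n_clusters)
}

#' Within-cluster similarity statistics and p-value for one cluster
#'
#' Summarizes the pairwise similarities among the cluster's members
#' (min/mean/max/stdev) and tests, one-sided, whether they exceed the
#' similarities of mixed pairs (one member, one outsider). The default test
#' is a one-sided Welch two-sample t-test; \code{"mann_whitney"} selects the
#' one-sided Wilcoxon rank-sum test instead.
#'
#' The standard deviation is reported as \code{NA} for clusters with fewer
#' than 3 members (a 2-species cluster has a single within pair). For a
#' 2-species cluster the Welch test degenerates to a one-sample t-test of
#' the mixed-pair similarities against the single within value. A singleton
#' cluster has no within pairs: all statistics and the p-value are
#' \code{NA}.
#'
#' @param matrix a [similarity_matrix()].
#' @param members character vector of species labels in the cluster; must be
#'   a non-empty proper subset of the matrix labels.
#' @param test \code{"welch_t"} (default) or \code{"mann_whitney"}.
#' @return one-row data.frame: \code{n_species}, \code{min}, \code{mean},
#'   \code{max}, \code{stdev}, \code{p_value}.
#' @export
cluster_pvalue <- function(matrix, members, test = c("welch_t", "mann_whitney")) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  test <- match.arg(test)
  labels <- rownames(matrix)
  if (length(members) == 0 || !all(members %in% labels))
    stop("invalid-input: members must be labels of the matrix", call. = FALSE)
  if (length(members) >= length(labels))
    stop("invalid-input: cluster must be a proper subset of the species", call. = FALSE)
  outside <- setdiff(labels, members)
  m <- unclass(matrix)
  within <- if (length(members) >= 2) {
    sub <- m[members, members, drop = FALSE]
    sub[upper.tri(sub)]
  } else numeric(0)
  between <- as.numeric(m[members, outside, drop = FALSE])
  if (length(within) == 0) {
    return(data.frame(n_species = length(members), min = NA_real_,
                      mean = NA_real_, max = NA_real_, stdev = NA_real_,
                      p_value = NA_real_))
  }
  rank_p <- function()
    stats::wilcox.test(within, between, alternative = "greater",
                       exact = FALSE)$p.value
  p <- if (test == "welch_t") {
    welch <- function() {
      if (length(within) >= 2)
        stats::t.test(within, between, alternative = "greater")$p.value
      else  # a 2-species cluster has one within pair: test between < that value
        stats::t.test(between, mu = within, alternative = "less")$p.value
    }
    # essentially-constant similarities break the t statistic; rank test instead
    tryCatch(welch(), error = function(e) rank_p())
  } else rank_p()
  data.frame(
    n_species = length(members),
    min   = min(within),
    mean  = mean(within),
    max   = max(within),
    stdev = if (length(members) >= 3) stats::sd(within) else NA_real_,
    p_value = min(max(p, .Machine$double.xmin), 1)
  )
}

#' Per-cluster statistics table
#'
#' One row per cluster with the columns of the classic cluster-statistics
#' table: cluster id, number of species, min/mean/max/stdev of within-cluster
#' similarity, and the within-vs-between p-value. Clusters covering all
#' species (a 1-cluster partition) have no outside pairs and get \code{NA}
#' p-values.
#'
#' @inheritParams cluster_pvalue
#' @param membership named integer vector as returned by [cut_clusters()].
#' @return data.frame with one row per cluster and an attribute
#'   \code{members} (list of label vectors per cluster).
#' @export
cluster_table <- function(matrix, membership, test = c("welch_t", "mann_whitney")) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  test <- match.arg(test)
  if (is.null(names(membership)) || !setequal(names(membership), rownames(matrix)))
    stop("invalid-input: membership must be named by the matrix labels", call. = FALSE)
  ids <- sort(unique(membership))
  members <- lapply(ids, function(i) names(membership)[membership == i])
  rows <- lapply(members, function(mem) {
    if (length(mem) == nrow(matrix)) {
      within <- unclass(matrix)[upper.tri(matrix)]
      data.frame(n_species = length(mem), min = min(within), mean = mean(within),
                 max = max(within),
                 stdev = if (length(mem) >= 3) stats::sd(within) else NA_real_,
                 p_value = NA_real_)
    } else cluster_pvalue(matrix, mem, test = test)
  })
  out <- cbind(cluster = ids, do.call(rbind, rows))
  attr(out, "members") <- stats::setNames(members, ids)
  out
}

#' Partition-based cluster extraction (k-means / PAM)
#'
#' Alternative extractors operating on the similarity rows as points
#' (k-means) or on \code{d = 1 - similarity} (PAM). Offered for comparison;
#' the hierarchical cut ([cut_clusters()]) is the primary route.
#'
#' @inheritParams cut_clusters
#' @param method \code{"kmeans"} or \code{"pam"}.
#' @param seed RNG seed for k-means initialization.
#' @return named integer membership vector.
#' @export
partition_clusters <- function(matrix, n_clusters, method = c("kmeans", "pam"),
                               seed = 1L) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  method <- match.arg(method)
  if (method == "kmeans") {
    km <- with_seed(seed, stats::kmeans(unclass(matrix), centers = n_clusters,
                                        nstart = 10))
    stats::setNames(km$cluster, rownames(matrix))
  } else {
    pm <- cluster::pam(.sim_to_dist(matrix), k = n_clusters)
    stats::setNames(pm$clustering, rownames(matrix))
  }
}
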