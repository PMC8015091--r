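# Tree construction from similarity/distance matrices (UPGMA, neighbor
# joining) and Newick serialization. Trees are ape "phylo" objects.

.tree_dist <- function(x) {
  if (inherits(x, "similarity_matrix")) return(.sim_to_dist(x))
  if (inherits(x, "dist")) return(x)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) stop("invalid-input: distance matrix needs labels", call. = FALSE)
    if (max(abs(x - t(x))) > 1e-9)
      stop("invalid-input: matrix is not symmetric", call. = FALSE)
    return(stats::as.dist(x))
  }
  stop("invalid-input: need a similarity_matrix, dist, or labeled numeric matrix",
       call. = FALSE)
}

#' UPGMA tree
#'
#' Average-linkage agglomeration on \code{d = 1 - similarity} (or on the
#' given distances). The result is ultrametric: all leaves are equidistant
#' from the root, with each merge at height h placing its leaves at depth
#' h/2. Deterministic; ties follow the fixed ordering of
#' \code{stats::hclust}.
#'
#' @param x a [similarity_matrix()], a \code{dist}, or a labeled symmetric
#'   numeric distance matrix.
#' @return a rooted \code{phylo} tree (class from \pkg{ape}).
#' @export
upgma_tree <- function(x) {
  d <- .tree_dist(x)
  if (attr(d, "Size") < 2) stop("invalid-input: need at least 2 species", call. = FALSE)
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Neighbor-joining tree
#'
#' Classic Saitou–Nei neighbor joining on \code{d = 1 - similarity} (or the
#' given distances); additive distance matrices are recovered exactly. The
#' output is unrooted with a basal trifurcation. Negative branch lengths (a
#' known NJ artifact on non-additive input) are clamped to 0 and the deficit
#' transferred to the sister branch, preserving path lengths through the
#' parent node.
#'
#' @inheritParams upgma_tree
#' @return an unrooted \code{phylo} tree.
#' @export
nj_tree <- function(x) {
  d <- .tree_dist(x)
  if (attr(d, "Size") < 3) stop("invalid-input: need at least 3 species", call. = FALSE)
  tr <- ape::nj(d)
  .clamp_negative_branches(tr)
}

# Set negative edge lengths to 0 and transfer the negative amount to the
# sibling edge(s) at the same parent (split evenly when several), so path
# lengths through the parent node are preserved. A final clamp guards the
# rare case where a sibling is driven below zero in turn.
.clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (i in neg) {
    transfer <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    sibs <- setdiff(which(tree$edge[, 1] == tree$edge[i, 1]), i)
    if (length(sibs) > 0)
      tree$edge.length[sibs] <- tree$edge.length[sibs] + transfer / length(sibs)
  }
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

.NEWICK_RESERVED <- "[](),:;'\" \t\n"

.quote_label <- function(lab) {
  needs <- grepl("[][(),:;'\" \t\n]", lab)
  esc <- gsub("'", "''", lab, fixed = TRUE)
  ifelse(needs, paste0("'", esc, "'"), lab)
}

#' Serialize a tree to Newick text
#'
#' Standard parenthetical Newick with branch lengths, terminated by ";".
#' Labels containing reserved characters (parentheses, commas, colons,
#' whitespace, quotes) are single-quoted, with embedded quotes doubled; the
#' text round-trips through [read_newick()].
#'
#' @param tree a \code{phylo} object.
#' @param precision significant digits for branch lengths.
#' @param path optional file to write the text to.
#' @return the Newick string, invisibly when \code{path} is given.
#' @export
write_newick <- function(tree, precision = 10, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("invalid-input: duplicate leaf labels", call. = FALSE)
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.*g", precision, x)
  rec <- function(node) {
    if (node <= n_tip) return(.quote_label(tree$tip.label[node]))
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      sub <- rec(child)
      if (!is.null(tree$edge.length))
        sub <- paste0(sub, ":", fmt(tree$edge.length[e]))
      sub
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n_tip + 1L
  txt <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse Newick text into a tree
#'
#' Companion reader for [write_newick()]. Single-quoted labels (with
#' doubled embedded quotes) are substituted by opaque placeholders before
#' the structural parse (\pkg{ape}) and restored afterwards, so labels
#' containing reserved characters survive a write/read round trip.
#'
#' @param text Newick string; or use \code{path} to read from a file.
#' @param path optional file containing Newick text.
#' @return a \code{phylo} object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("invalid-input: give text or path", call. = FALSE)
    text <- paste(readLines(path), collapse = "")
  }
  # shelter quoted labels from the structural parser
  pat <- "'(?:[^']|'')*'"
  mt <- gregexpr(pat, text, perl = TRUE)[[1]]
  restored <- character(0)
  if (mt[1] != -1) {
    quoted <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
    keys <- sprintf("WGKSQLBL%dX", seq_along(quoted))
    restored <- stats::setNames(
      gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1), fixed = TRUE), keys)
    for (i in seq_along(quoted))
      text <- sub(pat, keys[i], text, perl = TRUE)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("invalid-input: could not parse Newick text", call. = FALSE)
  unshelter <- function(lab) {
    hit <- lab %in% names(restored)
    lab[hit] <- restored[lab[hit]]
    lab
  }
  tr$tip.label <- unshelter(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unshelter(tr$node.label)
  tr
}
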