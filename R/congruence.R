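# Clustering of taxa from compensatory-change matrices and congruence of
# the resulting dendrogram with a reference phylogeny.

#' Hierarchical clustering of a (dis)similarity matrix
#'
#' Agglomerative clustering via [stats::hclust()]. Pairwise
#' compensatory-change counts grow with divergence, so a `cbc_matrix` is
#' used directly as a dissimilarity; a genuine similarity matrix (larger =
#' more alike) is converted as `max(m) - m` when `similarity = TRUE`.
#' Rows/columns are sorted by label first so ties break deterministically.
#'
#' @param m Symmetric numeric matrix with labelled rows, or a `cbc_matrix`
#'   (its total count matrix is used).
#' @param linkage `complete` (default), `average` or `single`.
#' @param similarity Is `m` a similarity matrix?
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(m, linkage = c("complete", "average", "single"),
                                 similarity = FALSE) {
  linkage <- match.arg(linkage)
  if (inherits(m, "cbc_matrix")) m <- m$total
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    abort("matrix is not symmetric", class = "mito_data_error")
  }
  ord <- order(rownames(m))
  m <- m[ord, ord]
  if (similarity) m <- max(m) - m
  stats::hclust(stats::as.dist(m), method = linkage)
}

# topological node depths (number of internal nodes strictly above each
# node on the root path; root = 0) and tip-pair LCA depths of a rooted tree
lca_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- integer(n_tip + tree$Nnode)
  # cladewise edge order lists every parent before its children
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(edge))) {
    depth[edge[i, 2]] <- depth[edge[i, 1]] + 1L
  }
  mrca <- ape::mrca(tree)
  taxa <- sort(tree$tip.label)
  pairs <- utils::combn(taxa, 2)
  v <- apply(pairs, 2, function(p) depth[mrca[p[1], p[2]]])
  stats::setNames(v, paste(pairs[1, ], pairs[2, ], sep = "|"))
}

as_rooted_phylo <- function(x) {
  if (inherits(x, "hclust")) x <- ape::as.phylo(x)
  if (!inherits(x, "phylo")) abort("expected an hclust or phylo object")
  x
}

#' Baker's gamma congruence index of two trees
#'
#' For every unordered leaf pair, the topological depth of the pair's lowest
#' common ancestor is computed in each tree (number of internal nodes
#' between it and the root); gamma is the Spearman rank correlation of the
#' two pair-vectors, 1 for identical clusterings. Branch lengths are never
#' used, so dendrograms and phylograms compare directly.
#'
#' @param d1,d2 `hclust` dendrograms or rooted `phylo` trees with identical
#'   leaf sets.
#' @return Gamma in \[-1, 1\].
#' @export
bakers_gamma <- function(d1, d2) {
  t1 <- as_rooted_phylo(d1); t2 <- as_rooted_phylo(d2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets", class = "mito_data_error")
  }
  v1 <- lca_depths(t1); v2 <- lca_depths(t2)
  stats::cor(v1, v2[names(v1)], method = "spearman")
}

# --- tanglegram -----------------------------------------------------------

# mutable child-order representation for rotation search
tree_struct <- function(tree) {
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  list(children = split(tree$edge[, 2], factor(tree$edge[, 1])),
       root = root, n_tip = length(tree$tip.label), labels = tree$tip.label)
}

leaf_order <- function(ts, flipped) {
  out <- character(0)
  walk <- function(nd) {
    if (nd <= ts$n_tip) {
      out[[length(out) + 1]] <<- ts$labels[nd]
      return(invisible())
    }
    kids <- ts$children[[as.character(nd)]]
    if (isTRUE(flipped[nd])) kids <- rev(kids)
    for (k in kids) walk(k)
  }
  walk(ts$root)
  unlist(out)
}

crossing_count <- function(ord1, ord2) {
  p <- match(ord1, ord2)
  n <- length(p)
  sum(vapply(seq_len(n - 1), function(i) sum(p[(i + 1):n] < p[i]), 0))
}

#' Tanglegram data with greedy untangling
#'
#' Searches leaf-order rotations of both trees (greedy node flips, alternate
#' sides until no improvement) to minimize the number of crossing lines
#' between matched leaves, and reports the matched leaf positions plus the
#' crossing count.
#'
#' @inheritParams bakers_gamma
#' @return A `tanglegram`: list with `leaves` (tibble `taxon`, `pos1`,
#'   `pos2`) and `crossings`.
#' @export
tanglegram_export <- function(d1, d2) {
  t1 <- as_rooted_phylo(d1); t2 <- as_rooted_phylo(d2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets", class = "mito_data_error")
  }
  s1 <- tree_struct(t1); s2 <- tree_struct(t2)
  f1 <- logical(s1$n_tip + t1$Nnode); f2 <- logical(s2$n_tip + t2$Nnode)
  best <- crossing_count(leaf_order(s1, f1), leaf_order(s2, f2))
  repeat {
    improved <- FALSE
    for (side in 1:2) {
      ts <- if (side == 1) s1 else s2
      fl <- if (side == 1) f1 else f2
      for (nd in as.integer(names(ts$children))) {
        fl[nd] <- !fl[nd]
        cc <- if (side == 1) crossing_count(leaf_order(ts, fl), leaf_order(s2, f2))
              else crossing_count(leaf_order(s1, f1), leaf_order(ts, fl))
        if (cc < best) {
          best <- cc
          improved <- TRUE
        } else {
          fl[nd] <- !fl[nd]
        }
      }
      if (side == 1) f1 <- fl else f2 <- fl
    }
    if (!improved) break
  }
  ord1 <- leaf_order(s1, f1); ord2 <- leaf_order(s2, f2)
  leaves <- tibble::tibble(taxon = ord1, pos1 = seq_along(ord1),
                           pos2 = match(ord1, ord2))
  structure(list(leaves = leaves, crossings = best), class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat(sprintf("<tanglegram> %d leaves, %d crossing(s) after untangling\n",
              nrow(x$leaves), x$crossings))
  invisible(x)
}

#' @export
#' @method tidy tanglegram
tidy.tanglegram <- function(x, ...) x$leaves
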