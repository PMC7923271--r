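# Rooted-tree handling and Fitch parsimony ancestral reconstruction on a
# fixed topology, with per-branch substitution enumeration.
#
# Trees are ape "phylo" objects. A branch is identified by its child node;
# it is external when the child is a leaf. The reconstruction alphabet is
# A < C < G < U/T < gap, with the gap a true fifth state (indels in tRNA
# stems are part of the analysis, not missing data).

FITCH_ALPHABET <- c("A", "C", "G", "T", "-")

#' Read a rooted tree from newick text or file
#'
#' @param x Newick string or path to a newick file.
#' @param outgroup Optional leaf label; the tree is re-rooted on the branch
#'   leading to it.
#' @return An ape `phylo` object (rooted).
#' @export
read_newick <- function(x, outgroup = NULL) {
  tree <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tree)) abort("could not parse newick input", class = "mito_format_error")
  if (anyDuplicated(tree$tip.label)) {
    abort("duplicate leaf labels in tree", class = "mito_data_error")
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Branch table of a rooted tree
#'
#' @param tree A `phylo`.
#' @return Tibble `parent`, `child`, `class` (`external`/`internal`),
#'   `child_label` (leaf label or `node<N>`).
#' @export
branch_table <- function(tree) {
  n_tip <- length(tree$tip.label)
  tibble::tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    class = ifelse(tree$edge[, 2] <= n_tip, "external", "internal"),
    child_label = node_label(tree, tree$edge[, 2]))
}

node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  ifelse(node <= n_tip, tree$tip.label[node], paste0("node", node))
}

# normalize an alignment to an uppercase character matrix over the Fitch
# alphabet (U -> T, anything else -> gap)
as_aln_matrix <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- toupper(as.character(aln))
  m <- toupper(as.matrix(aln))
  m <- chartr("U", "T", m)
  m[!m %in% FITCH_ALPHABET] <- "-"
  m
}

#' Fitch parsimony ancestral reconstruction
#'
#' Per-column Fitch bottom-up (intersection/union) and top-down passes on
#' the fixed rooted topology, with the gap treated as a fifth character
#' state. Ties at the root, and at internal nodes whose state set does not
#' contain the parent state, resolve to the state carried by the node's
#' first descendant leaf when that state is in the set (outgroup-style
#' polarization, which keeps jointly-changing alignment columns -- such as
#' the two sides of a tRNA stem pair -- synchronized on the same branch),
#' falling back to the first state in the fixed alphabet order
#' `A < C < G < U/T < gap`. The per-column parsimony score (number of union
#' events) is recorded and is independent of the tie policy.
#'
#' @param aln Alignment: character matrix or `DNAbin`, rows named by the
#'   tree's leaf labels.
#' @param tree Rooted `phylo` covering exactly the alignment's rows.
#' @return An `ancestral_alignment`: list with `alignment` (rows = leaves
#'   then internal nodes `node<N>`), `score` (per-column parsimony score)
#'   and `tree`.
#' @export
fitch_ancestral <- function(aln, tree) {
  m <- as_aln_matrix(aln)
  tips <- tree$tip.label
  if (!all(tips %in% rownames(m))) {
    abort(paste("alignment missing leaf row(s):",
                paste(setdiff(tips, rownames(m)), collapse = ", ")),
          class = "mito_data_error")
  }
  m <- m[tips, , drop = FALSE]
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  n_col <- ncol(m)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  root <- edge[nrow(edge), 1]
  A <- length(FITCH_ALPHABET)
  # state sets as logical matrices [node x A] per column, vectorized over
  # columns: sets[[node]] is an n_col x A logical matrix
  tip_idx <- match(m, FITCH_ALPHABET)
  dim(tip_idx) <- dim(m)
  anc <- matrix("", nrow = tree$Nnode, ncol = n_col,
                dimnames = list(paste0("node", (n_tip + 1):n_node), NULL))
  score <- integer(n_col)
  children <- split(edge[, 2], edge[, 1])
  # bottom-up: per node an n_col x A logical matrix
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) {
    s <- matrix(FALSE, n_col, A)
    s[cbind(seq_len(n_col), tip_idx[i, ])] <- TRUE
    sets[[i]] <- s
  }
  node_order <- unique(edge[, 1])  # postorder: children before parents
  for (nd in node_order) {
    kids <- children[[as.character(nd)]]
    s <- sets[[kids[1]]]
    for (k in kids[-1]) {
      # running pairwise Fitch: intersect where possible, else union (+1)
      inter <- s & sets[[k]]
      empty <- rowSums(inter) == 0
      score <- score + empty
      nxt <- inter
      if (any(empty)) {
        nxt[empty, ] <- s[empty, , drop = FALSE] | sets[[k]][empty, , drop = FALSE]
      }
      s <- nxt
    }
    sets[[nd]] <- s
  }
  # first descendant leaf of every node (cladewise order), for tie breaking
  lead_tip <- integer(n_node)
  lead_tip[seq_len(n_tip)] <- seq_len(n_tip)
  cw <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in rev(seq_len(nrow(cw)))) {
    if (lead_tip[cw[i, 1]] == 0L) lead_tip[cw[i, 1]] <- lead_tip[cw[i, 2]]
  }
  # pick, per column, the preferred member of a state set: the node's first
  # descendant leaf's state if present, else the first state in alphabet order
  pick_state <- function(set_mat, rows, nd) {
    lead <- tip_idx[lead_tip[nd], rows]
    has_lead <- set_mat[cbind(seq_along(rows), lead)]
    out <- integer(length(rows))
    out[has_lead] <- lead[has_lead]
    if (any(!has_lead)) {
      out[!has_lead] <- apply(set_mat[!has_lead, , drop = FALSE], 1, which.max)
    }
    out
  }
  # top-down assignment
  assign_state <- matrix(0L, n_node, n_col)
  assign_state[root, ] <- pick_state(sets[[root]], seq_len(n_col), root)
  preorder <- rev(node_order)
  for (nd in preorder) {
    for (kid in children[[as.character(nd)]]) {
      if (kid <= n_tip) next
      par_state <- assign_state[nd, ]
      kid_set <- sets[[kid]]
      keep <- kid_set[cbind(seq_len(n_col), par_state)]
      st <- integer(n_col)
      st[keep] <- par_state[keep]
      if (any(!keep)) {
        st[!keep] <- pick_state(kid_set[!keep, , drop = FALSE], which(!keep), kid)
      }
      assign_state[kid, ] <- st
    }
  }
  for (nd in (n_tip + 1):n_node) {
    anc[nd - n_tip, ] <- FITCH_ALPHABET[assign_state[nd, ]]
  }
  structure(
    list(alignment = rbind(m, anc), score = score, tree = tree),
    class = "ancestral_alignment")
}

#' @export
print.ancestral_alignment <- function(x, ...) {
  cat(sprintf("<ancestral_alignment> %d leaves + %d internal nodes, %d columns, parsimony score %d\n",
              length(x$tree$tip.label), x$tree$Nnode, ncol(x$alignment),
              sum(x$score)))
  invisible(x)
}

#' @export
#' @method glance ancestral_alignment
glance.ancestral_alignment <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$tree$tip.label),
                 n_internal = x$tree$Nnode,
                 n_columns = ncol(x$alignment),
                 parsimony_score = sum(x$score),
                 variable_columns = sum(x$score > 0))
}

#' Per-branch substitutions implied by an ancestral reconstruction
#'
#' One record per branch and column where the assigned parent and child
#' states differ; changes to or from the gap state are flagged as indels.
#'
#' @param aa An `ancestral_alignment` from [fitch_ancestral()].
#' @return Tibble `branch` (child node id), `branch_class`, `child_label`,
#'   `column`, `parent_state`, `child_state`, `indel`.
#' @export
branch_substitutions <- function(aa) {
  tree <- aa$tree
  m <- aa$alignment
  bt <- branch_table(tree)
  rows <- purrr::pmap(bt, function(parent, child, class, child_label) {
    ps <- m[node_label(tree, parent), ]
    cs <- m[child_label, ]
    d <- which(ps != cs)
    if (!length(d)) return(NULL)
    tibble::tibble(branch = child, branch_class = class,
                   child_label = child_label, column = d,
                   parent_state = ps[d], child_state = cs[d],
                   indel = ps[d] == "-" | cs[d] == "-")
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(branch = integer(), branch_class = character(),
                          child_label = character(), column = integer(),
                          parent_state = character(), child_state = character(),
                          indel = logical())
  }
  out
}

#' Write an ancestral alignment as aligned FASTA
#'
#' Internal-node rows are written under their `node<N>` ids.
#' @param aa An `ancestral_alignment`.
#' @param path Output FASTA.
#' @export
write_ancestral_fasta <- function(aa, path) {
  seqs <- apply(aa$alignment, 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path)
  invisible(path)
}
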