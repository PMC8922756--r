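## Bipartitions and the Robinson-Foulds distance.
##
## A bipartition is the split of the tip set induced by one internal edge of
## the unrooted tree. Canonical form: the side containing the overall
## lexicographically smallest tip label, with labels sorted; two
## bipartitions are equal iff their canonical keys are equal. Trivial
## splits (a single tip on one side) are excluded throughout.

## Tip-label sets descending from each internal edge of the unrooted tree.
## Returns a list of character vectors (one side of each non-trivial split),
## not yet canonicalized.
edge_tip_sets <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_nodes <- max(tr$edge)
  below <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  internal <- tr$edge[, 2L] > n_tip
  sets <- lapply(which(internal), function(e) below[[tr$edge[e, 2L]]])
  sizes <- lengths(sets)
  keep <- sizes >= 2L & sizes <= n_tip - 2L
  out <- sets[keep]
  attr(out, "edge_index") <- which(internal)[keep]  # row in postorder edge matrix
  attr(out, "tree_postorder") <- tr
  out
}

## Canonical string key of one side of a split given the full tip set.
bipartition_key <- function(side, all_tips) {
  side <- sort(side)
  other <- sort(setdiff(all_tips, side))
  a <- if (min(side) < min(other)) side else other
  paste(a, collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree A `phylo` (rooted trees are unrooted first).
#' @return Character vector of canonical bipartition keys, one per internal
#'   edge.
#' @export
bipartitions <- function(tree) {
  sets <- edge_tip_sets(tree)
  tips <- sort(tree$tip.label)
  vapply(sets, bipartition_key, "", all_tips = tips)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions, computed on the
#' unrooted topologies. Tip sets must match; use [prune_to_shared()] first
#' when they do not.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @param normalized Also return the distance divided by `2 (n - 3)`.
#' @return Integer RF distance, or a list `(rf, normalized)` when
#'   `normalized = TRUE`.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("tip sets differ (", paste(d, collapse = ", "),
         "); prune_to_shared() first")
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(as.integer(rf))
  n <- length(l1)
  list(rf = as.integer(rf), normalized = rf / (2 * (n - 3)))
}

#' Prune two trees to their shared tips
#' @param t1,t2 `phylo` objects.
#' @return List of the two pruned trees.
#' @export
prune_to_shared <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) stop("fewer than 4 shared tips")
  list(ape::keep.tip(t1, shared), ape::keep.tip(t2, shared))
}

#' Collapse poorly supported internal edges into polytomies
#'
#' Every internal edge whose support is strictly below `threshold` is
#' contracted; tips are never touched. Supports are read from
#' `tree$node.label`; `scale = "probability"` values are rescaled to
#' percent before comparison.
#'
#' @param tree A `phylo` with supports in `node.label`.
#' @param threshold Support threshold on the percent scale (default 33).
#' @param scale `"bootstrap"` (percent, 0-100) or `"probability"` (0-1).
#' @return The collapsed `phylo` (may contain polytomies).
#' @export
collapse_low_support <- function(tree, threshold = 33,
                                 scale = c("bootstrap", "probability")) {
  scale <- match.arg(scale)
  tree <- ape::unroot(tree)
  if (is.null(tree$node.label))
    stop("tree carries no support values in node.label")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (scale == "probability") {
    if (any(sup > 1 + 1e-9, na.rm = TRUE))
      stop("probability-scale supports must lie in [0, 1]")
    sup <- sup * 100
  }
  n_tip <- ape::Ntip(tree)
  repeat {
    internal_edge <- tree$edge[, 2L] > n_tip
    esup <- rep(NA_real_, nrow(tree$edge))
    esup[internal_edge] <- sup[tree$edge[internal_edge, 2L] - n_tip]
    drop <- which(internal_edge & !is.na(esup) & esup < threshold)
    if (!length(drop)) break
    e <- drop[1L]
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    ## reattach child's descendants to parent, delete the edge and node
    sub <- tree$edge[, 1L] == child
    tree$edge[sub, 1L] <- par
    keep_edges <- seq_len(nrow(tree$edge)) != e
    tree$edge <- tree$edge[keep_edges, , drop = FALSE]
    if (!is.null(tree$edge.length))
      tree$edge.length <- tree$edge.length[keep_edges]
    ## renumber internal nodes above the removed one
    shift <- tree$edge > child
    tree$edge[shift] <- tree$edge[shift] - 1L
    sup <- sup[-(child - n_tip)]
    tree$node.label <- tree$node.label[-(child - n_tip)]
    tree$Nnode <- tree$Nnode - 1L
  }
  tree
}
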