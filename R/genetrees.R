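## Distance-based gene-tree inference: pairwise distances, neighbor
## joining, nonparametric bootstrap supports. Externally inferred newick
## trees (ML/BI engines) are equally valid inputs to everything downstream;
## this module just provides a fast, deterministic built-in route.

#' Pairwise distance matrix from an alignment
#'
#' @param aln A `gene_alignment` with >= 3 rows.
#' @param model `"p"` (raw proportion), `"JC69"` or `"K2P"`; pairwise
#'   deletion of gaps/Ns throughout.
#' @return Symmetric numeric matrix with zero diagonal. Saturated pairs
#'   (undefined under the correction) are `Inf` and listed in the
#'   `saturated_pairs` attribute.
#' @export
distance_matrix <- function(aln, model = c("JC69", "p", "K2P")) {
  model <- match.arg(model)
  stopifnot(nrow(aln) >= 3L)
  mod <- c(p = "raw", JC69 = "JC69", K2P = "K80")[[model]]
  d <- ape::dist.dna(as_DNAbin(aln), model = mod, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  bad <- !is.finite(d)
  diag(bad) <- FALSE
  d[bad] <- Inf
  sat <- which(bad & upper.tri(bad), arr.ind = TRUE)
  attr(d, "saturated_pairs") <- if (nrow(sat))
    data.frame(a = rownames(d)[sat[, 1L]], b = colnames(d)[sat[, 2L]])
  else NULL
  d
}

#' Neighbor-joining tree
#'
#' @param dm Distance matrix from [distance_matrix()] (or any symmetric
#'   matrix with finite entries).
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(dm) {
  if (any(!is.finite(dm[upper.tri(dm)]))) {
    sat <- attr(dm, "saturated_pairs")
    stop("non-finite distances; saturated pairs: ",
         if (is.null(sat)) "unknown" else
           paste(paste(sat$a, sat$b, sep = "-"), collapse = ", "))
  }
  ape::nj(stats::as.dist(dm))
}

## TRUE when the alignment carries no variation usable for resolution.
is_uninformative_alignment <- function(aln) {
  m <- unclass(aln)
  all(apply(m, 2L, function(col) {
    v <- unique(col[col %in% VALID_STATES]); length(v) <= 1L
  }))
}

star_tree <- function(labels) {
  tr <- ape::read.tree(text = paste0("(", paste(labels, collapse = ","), ");"))
  tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns are resampled with replacement `n_reps` times; the support of
#' each internal edge of the full-data tree is the percentage of replicate
#' trees containing its bipartition. An alignment with no variation yields
#' an unresolved star tree without supports.
#'
#' @param aln A `gene_alignment`.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (resampling is deterministic under it).
#' @param model Distance model, as in [distance_matrix()].
#' @return A `phylo` whose `node.label` holds bootstrap percentages
#'   (internal nodes; empty at unsupported positions), with attribute
#'   `support_scale = "bootstrap"`.
#' @export
bootstrap_supports <- function(aln, n_reps = 1000L, seed = 1L,
                               model = "JC69") {
  if (is_uninformative_alignment(aln)) {
    tr <- star_tree(rownames(aln))
    attr(tr, "support_scale") <- "bootstrap"
    return(tr)
  }
  base <- ape::unroot(nj_tree(distance_matrix(aln, model)))
  keys <- bipartitions(base)
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(aln)
  with_seed(derive_seed(seed, "bootstrap"), {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- gene_alignment(unclass(aln)[, cols, drop = FALSE])
      dm <- distance_matrix(rep_aln, model)
      if (any(!is.finite(dm[upper.tri(dm)]))) next
      bk <- bipartitions(nj_tree(dm))
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  pct <- round(100 * counts / n_reps)
  ## attach supports to node labels: map each internal edge's child node to
  ## its bipartition key
  sets <- edge_tip_sets(base)
  tr <- attr(sets, "tree_postorder")
  eidx <- attr(sets, "edge_index")
  n_tip <- ape::Ntip(tr)
  labs <- rep("", tr$Nnode)
  tips <- sort(tr$tip.label)
  for (k in seq_along(sets)) {
    node <- tr$edge[eidx[k], 2L]
    labs[node - n_tip] <- as.character(pct[[bipartition_key(sets[[k]], tips)]])
  }
  tr$node.label <- labs
  attr(tr, "support_scale") <- "bootstrap"
  tr
}
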