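## Quartet scoring and a quartet-support species-tree estimator: a
## desk-scale summary-method stand-in in the spirit of coalescent summary
## methods, reporting per-edge relative quartet support instead of a true
## local posterior probability. Exhaustive search enumerates all unrooted
## topologies (<= 9 taxa); larger problems use greedy NNI hill climbing.

## Resolution code of each 4-taxon subset induced by `tree`, relative to a
## fixed sorted taxon vector: 1 = {1,2}|{3,4}, 2 = {1,3}|{2,4},
## 3 = {1,4}|{2,3}, 0 = unresolved. `quartets` is the 4 x n_quartets output
## of combn(indices, 4).
quartet_resolutions <- function(tree, taxa, quartets) {
  sets <- edge_tip_sets(tree)
  if (!length(sets)) return(integer(ncol(quartets)))
  B <- do.call(rbind, lapply(sets, function(s) taxa %in% s))
  res <- integer(ncol(quartets))
  for (q in seq_len(ncol(quartets))) {
    sub <- B[, quartets[, q], drop = FALSE]
    rs <- rowSums(sub)
    rows <- which(rs == 2L)
    if (!length(rows)) next
    side <- sub[rows[1L], ]
    res[q] <- if (side[1L] == side[2L]) 1L
              else if (side[1L] == side[3L]) 2L else 3L
  }
  res
}

quartet_cache <- new.env(parent = emptyenv())

## All unrooted binary topologies on sorted `taxa` plus their quartet
## resolution matrices; cached per taxon set.
candidate_topologies <- function(taxa, quartets) {
  key <- paste(taxa, collapse = "|")
  if (!is.null(quartet_cache[[key]])) return(quartet_cache[[key]])
  cands <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  res <- do.call(rbind, lapply(cands, quartet_resolutions,
                               taxa = taxa, quartets = quartets))
  out <- list(trees = cands, res = res)
  quartet_cache[[key]] <- out
  out
}

#' Total quartet agreement of a candidate species tree with gene trees
#'
#' @param candidate A binary `phylo`.
#' @param gene_trees `multiPhylo`/list of gene trees; tips are restricted
#'   to those shared with the candidate per gene.
#' @return List with `score` (count of resolved gene-tree quartets agreeing
#'   with the candidate) and `total_resolved`.
#' @export
quartet_score <- function(candidate, gene_trees) {
  taxa <- sort(candidate$tip.label)
  quartets <- utils::combn(seq_along(taxa), 4L)
  cand_res <- quartet_resolutions(candidate, taxa, quartets)
  score <- 0L; total <- 0L
  for (g in gene_trees) {
    shared <- intersect(g$tip.label, taxa)
    gt <- if (length(shared) < length(g$tip.label)) ape::keep.tip(g, shared) else g
    present <- taxa %in% shared
    ok_q <- colSums(matrix(present[quartets], nrow = 4L)) == 4L
    gres <- integer(ncol(quartets))
    gres[ok_q] <- quartet_resolutions(gt, taxa, quartets[, ok_q, drop = FALSE])
    resolved <- gres > 0L
    total <- total + sum(resolved)
    score <- score + sum(resolved & gres == cand_res)
  }
  list(score = as.integer(score), total_resolved = as.integer(total))
}

## Per-gene quartet resolution matrix on the shared taxa.
gene_resolution_matrix <- function(gene_trees, taxa, quartets) {
  do.call(rbind, lapply(gene_trees, function(g) {
    shared <- intersect(g$tip.label, taxa)
    gt <- if (length(shared) < length(g$tip.label)) ape::keep.tip(g, shared) else g
    present <- taxa %in% shared
    ok_q <- colSums(matrix(present[quartets], nrow = 4L)) == 4L
    out <- integer(ncol(quartets))
    out[ok_q] <- quartet_resolutions(gt, taxa, quartets[, ok_q, drop = FALSE])
    out
  }))
}

## Annotate per-edge quartet-support fractions as node labels.
annotate_edge_quartet_support <- function(tree, gene_res, taxa, quartets) {
  sets <- edge_tip_sets(tree)
  tr <- attr(sets, "tree_postorder")
  eidx <- attr(sets, "edge_index")
  n_tip <- ape::Ntip(tr)
  cand_res <- quartet_resolutions(tr, taxa, quartets)
  labs <- rep("", tr$Nnode)
  for (k in seq_along(sets)) {
    inA <- taxa %in% sets[[k]]
    cnt <- colSums(matrix(inA[quartets], nrow = 4L))
    around <- which(cnt == 2L)   # quartets straddling this edge 2 + 2
    if (!length(around)) next
    g <- gene_res[, around, drop = FALSE]
    c_r <- matrix(cand_res[around], nrow = nrow(g), ncol = length(around),
                  byrow = TRUE)
    resolved <- g > 0L
    frac <- if (sum(resolved)) sum(resolved & g == c_r) / sum(resolved) else NA
    labs[tr$edge[eidx[k], 2L] - n_tip] <- formatC(frac, digits = 3, format = "f")
  }
  tr$node.label <- labs
  attr(tr, "support_scale") <- "quartet_fraction"
  tr
}

#' Estimate a species tree by quartet support
#'
#' Exhaustive mode enumerates every unrooted binary topology on the shared
#' tip set (refused above 9 taxa) and returns the maximizer of the total
#' quartet agreement; greedy mode hill-climbs by nearest-neighbour
#' interchange from the best-scoring gene tree. Internal node labels of the
#' result carry the per-edge quartet-support fraction (agreeing resolved
#' quartets around the edge / resolved quartets around the edge).
#'
#' @param gene_trees `multiPhylo`/list with >= 2 trees.
#' @param mode `"exhaustive"` or `"greedy-NNI"`.
#' @return A `phylo` with attributes `quartet_score` and `support_scale`.
#' @export
estimate_species_tree <- function(gene_trees, mode = c("exhaustive", "greedy-NNI")) {
  mode <- match.arg(mode)
  stopifnot(length(gene_trees) >= 2L)
  taxa <- sort(Reduce(intersect, lapply(gene_trees, `[[`, "tip.label")))
  if (length(taxa) < 4L) stop("fewer than 4 shared tips across gene trees")
  quartets <- utils::combn(seq_along(taxa), 4L)
  gene_res <- gene_resolution_matrix(gene_trees, taxa, quartets)
  score_res <- function(cand_res) {
    sum(gene_res > 0L & gene_res == matrix(cand_res, nrow = nrow(gene_res),
                                           ncol = length(cand_res), byrow = TRUE))
  }
  if (mode == "exhaustive") {
    if (length(taxa) > 9L)
      stop("exhaustive enumeration refused above 9 taxa; use mode = \"greedy-NNI\"")
    cand <- candidate_topologies(taxa, quartets)
    scores <- apply(cand$res, 1L, score_res)
    best <- cand$trees[[which.max(scores)]]
    best_score <- max(scores)
  } else {
    starts <- lapply(gene_trees, function(g) ape::keep.tip(g, taxa))
    s0 <- vapply(starts, function(g)
      score_res(quartet_resolutions(ape::multi2di(g, random = FALSE), taxa, quartets)), 0)
    best <- ape::multi2di(starts[[which.max(s0)]], random = FALSE)
    best$edge.length <- NULL
    best_score <- score_res(quartet_resolutions(best, taxa, quartets))
    repeat {
      nbrs <- phangorn::nni(best)
      ns <- vapply(nbrs, function(tr)
        score_res(quartet_resolutions(tr, taxa, quartets)), 0)
      if (max(ns) <= best_score) break
      best <- nbrs[[which.max(ns)]]
      best_score <- max(ns)
    }
  }
  out <- annotate_edge_quartet_support(best, gene_res, taxa, quartets)
  attr(out, "quartet_score") <- as.integer(best_score)
  out
}
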