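## Per-edge gene-tree concordance bookkeeping in the PhyParts style: for
## every internal edge of the species tree, each gene tree is classified as
## concordant, in conflict (recording which gene bipartition conflicts), or
## uninformative; across genes the modal conflicting bipartition is the
## "top alternative" for the edge.

## Split a canonical bipartition key back into its two sides given the full
## tip set.
key_sides <- function(key, all_tips) {
  a <- strsplit(key, "|", fixed = TRUE)[[1L]]
  list(a = a, b = setdiff(all_tips, a))
}

## Two bipartitions on the same tip set are compatible iff one of the four
## pairwise side intersections is empty.
sides_compatible <- function(a1, b1, a2, b2) {
  !length(intersect(a1, a2)) || !length(intersect(a1, b2)) ||
    !length(intersect(b1, a2)) || !length(intersect(b1, b2))
}

#' Classify one gene tree against one species-tree bipartition
#'
#' The species bipartition is restricted to the tips shared with the gene
#' tree. If the restriction is trivial (fewer than 2 tips on either side)
#' the gene is uninformative; if the restricted bipartition occurs among
#' the gene tree's (sufficiently supported) bipartitions it is concordant;
#' if some supported gene bipartition on the shared tips is incompatible
#' with it the gene conflicts, reporting that bipartition; otherwise
#' (unresolved gene tree) it is uninformative.
#'
#' @param gene_tree A `phylo`.
#' @param species_bipartition List with sides `a` and `b` (character tip
#'   vectors), or a canonical key string together with `all_tips`.
#' @param support_cutoff Gene-tree edges with support below this (percent
#'   scale) are ignored; 0 disables the filter.
#' @param all_tips Full species tip set (needed when a key string is given).
#' @return List with `status` (`"concordant"`, `"conflict"`,
#'   `"uninformative"`) and `conflicting_bipartition` (canonical key on the
#'   shared tips, or `NA`).
#' @export
classify_edge <- function(gene_tree, species_bipartition, support_cutoff = 0,
                          all_tips = NULL) {
  if (is.character(species_bipartition)) {
    stopifnot(!is.null(all_tips))
    species_bipartition <- key_sides(species_bipartition, all_tips)
  }
  sa <- species_bipartition$a; sb <- species_bipartition$b
  shared <- intersect(gene_tree$tip.label, c(sa, sb))
  if (!length(shared)) stop("gene tree shares no tips with the species bipartition")
  ra <- intersect(sa, shared); rb <- intersect(sb, shared)
  if (length(ra) < 2L || length(rb) < 2L)
    return(list(status = "uninformative", conflicting_bipartition = NA_character_))
  gt <- if (length(shared) < length(gene_tree$tip.label))
    ape::keep.tip(gene_tree, shared) else gene_tree
  sets <- edge_tip_sets(gt)
  if (support_cutoff > 0 && !is.null(gt$node.label)) {
    tr <- attr(sets, "tree_postorder")
    eidx <- attr(sets, "edge_index")
    sup <- suppressWarnings(as.numeric(tr$node.label))
    esup <- sup[tr$edge[eidx, 2L] - ape::Ntip(tr)]
    keep <- is.na(esup) | esup >= support_cutoff
    sets <- sets[keep]
  }
  tips_sorted <- sort(shared)
  target <- bipartition_key(ra, tips_sorted)
  gene_keys <- vapply(sets, bipartition_key, "", all_tips = tips_sorted)
  if (target %in% gene_keys)
    return(list(status = "concordant", conflicting_bipartition = NA_character_))
  conflicting <- character(0)
  for (k in seq_along(sets)) {
    ga <- sets[[k]]; gb <- setdiff(shared, ga)
    if (length(ga) < 2L || length(gb) < 2L) next
    if (!sides_compatible(ra, rb, ga, gb))
      conflicting <- c(conflicting, gene_keys[k])
  }
  if (!length(conflicting))
    return(list(status = "uninformative", conflicting_bipartition = NA_character_))
  ## deterministic choice of "the" conflicting split: smallest smaller side,
  ## then canonical order
  small_side <- vapply(conflicting, function(k)
    min(lengths(key_sides(k, tips_sorted))), 0L)
  pick <- conflicting[order(small_side, conflicting)][1L]
  list(status = "conflict", conflicting_bipartition = pick)
}

#' Summarize gene-tree concordance over a species tree
#'
#' For each internal edge of the species tree, counts genes that are
#' concordant, in the modal ("top") alternative conflicting bipartition, in
#' any other conflicting bipartition, or uninformative. The four counts sum
#' to the number of gene trees at every edge.
#'
#' @param species_tree A `phylo`.
#' @param gene_trees `multiPhylo`/list with >= 1 tree.
#' @param support_cutoff Passed to [classify_edge()].
#' @return A `concordance_summary` data frame with one row per species-tree
#'   internal edge: `edge` (canonical bipartition key), `n_concordant`,
#'   `n_top_alternative`, `top_alternative` (key or `NA`),
#'   `n_other_conflict`, `n_uninformative`.
#' @export
summarize_concordance <- function(species_tree, gene_trees, support_cutoff = 0) {
  stopifnot(length(gene_trees) >= 1L)
  all_tips <- sort(species_tree$tip.label)
  sets <- edge_tip_sets(species_tree)
  keys <- vapply(sets, bipartition_key, "", all_tips = all_tips)
  rows <- lapply(seq_along(sets), function(k) {
    side_a <- sets[[k]]
    bip <- list(a = side_a, b = setdiff(species_tree$tip.label, side_a))
    cls <- lapply(gene_trees, classify_edge, species_bipartition = bip,
                  support_cutoff = support_cutoff)
    status <- vapply(cls, `[[`, "", "status")
    confl <- vapply(cls, `[[`, "", "conflicting_bipartition")
    confl <- confl[status == "conflict"]
    if (length(confl)) {
      tab <- sort(table(confl), decreasing = TRUE)
      top_n <- max(tab)
      top <- sort(names(tab)[tab == top_n])[1L]   # canonical-order tie break
      n_top <- as.integer(tab[[top]])
    } else {
      top <- NA_character_; n_top <- 0L
    }
    data.frame(edge = keys[k],
               n_concordant = sum(status == "concordant"),
               n_top_alternative = n_top,
               top_alternative = top,
               n_other_conflict = sum(status == "conflict") - n_top,
               n_uninformative = sum(status == "uninformative"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_summary", "data.frame")
  out
}
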