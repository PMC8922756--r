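## Synthetic species trees and discordance-regime gene trees.
##
## Species trees follow a pure-birth (Yule) process; gene-tree discordance
## is injected by applying a controlled number of random subtree-prune-
## regraft (SPR) moves per gene, which gives direct control over the
## topological distance that the downstream tree-space analysis measures
## (unlike a coalescent simulator, where the distance is only controlled in
## distribution).

#' Simulate a Yule species tree
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Integer seed; the same seed yields a byte-identical tree.
#' @param birth Speciation rate of the pure-birth process.
#' @return A rooted binary `phylo` with positive branch lengths and tips
#'   labelled `t1..tN`.
#' @export
simulate_species_tree <- function(n_taxa, seed, birth = 1) {
  if (n_taxa < 4L)
    stop("n_taxa must be >= 4: no informative unrooted bipartition exists below 4 tips")
  with_seed(derive_seed(seed, "sptree"), {
    tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
    tr$tip.label <- paste0("t", seq_len(n_taxa))
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  })
}

#' Simulate gene trees under SPR-discordance regimes
#'
#' Each regime is a pair (`n_genes`, `spr_moves`); every gene tree is the
#' species tree perturbed by exactly `spr_moves` random SPR moves (0 moves
#' leaves the topology intact), with branch lengths re-jittered
#' multiplicatively (log-normal, sd `jitter_sd`).
#'
#' In `"independent"` mode (the default) every gene tree receives its own
#' independent draw of `spr_moves` SPR moves from the species tree: gene
#' trees within a regime then share a *distance* to the species tree but
#' scatter independently around it, which is the right null for
#' discordance-rate questions. In `"anchored"` mode each regime first draws
#' one regime anchor (the species tree plus `spr_moves` SPR moves, redrawn
#' until the anchor realizes a Robinson-Foulds displacement of at least
#' `2 * spr_moves`) and the regime's gene trees are small jitters around
#' that anchor (one NNI with probability `nni_jitter_prob`): regimes then
#' form compact, well-separated clusters in tree space, the structure the
#' cluster-recovery analysis assumes.
#'
#' @param species_tree A `phylo`.
#' @param regimes List of lists/vectors with elements `n_genes` and
#'   `spr_moves`.
#' @param seed Integer master seed; per-gene streams are derived by stable
#'   hashing of (seed, regime, gene index).
#' @param mode `"independent"` or `"anchored"` (see Details).
#' @param nni_jitter_prob Probability that an anchored gene tree receives
#'   one NNI jitter move.
#' @param jitter_sd Log-scale sd of the multiplicative branch-length
#'   jitter.
#' @return A `multiPhylo` list of unrooted gene trees with attribute
#'   `truth`: data frame (`gene`, `regime`, `spr_moves`).
#' @export
simulate_gene_trees <- function(species_tree, regimes, seed,
                                mode = c("independent", "anchored"),
                                nni_jitter_prob = 0.25, jitter_sd = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(regimes) >= 1L)
  base <- ape::unroot(species_tree)
  trees <- list(); truth <- list(); g <- 0L
  for (r in seq_along(regimes)) {
    reg <- as.list(regimes[[r]])
    n_genes <- as.integer(reg$n_genes %||% reg[[1L]])
    spr <- as.integer(reg$spr_moves %||% reg[[2L]])
    stopifnot(n_genes >= 1L, spr >= 0L)
    ## the anchor must realize at least one changed bipartition per SPR
    ## move (RF >= 2 * spr_moves), so regime displacement grows with the
    ## prescribed number of moves
    anchor <- if (mode == "anchored" && spr > 0L) {
      with_seed(derive_seed(seed, "anchor", r), {
        best <- NULL
        for (try in 1:20) {
          cand <- phangorn::rSPR(base, moves = spr)
          d <- rf_distance(cand, base)
          if (is.null(best) || d > best$d) best <- list(tree = cand, d = d)
          if (best$d >= 2L * spr) break
        }
        best$tree
      })
    } else base
    for (i in seq_len(n_genes)) {
      g <- g + 1L
      trees[[g]] <- with_seed(derive_seed(seed, "gene", r, i), {
        tr <- if (mode == "independent") {
          if (spr > 0L) phangorn::rSPR(base, moves = spr) else base
        } else {
          if (stats::runif(1L) < nni_jitter_prob)
            phangorn::rNNI(anchor, moves = 1L) else anchor
        }
        if (is.null(tr$edge.length))
          tr$edge.length <- rep(mean(base$edge.length), nrow(tr$edge))
        tr$edge.length <- tr$edge.length *
          exp(stats::rnorm(length(tr$edge.length), 0, jitter_sd))
        tr
      })
      truth[[g]] <- data.frame(gene = sprintf("g%03d", g),
                               regime = r, spr_moves = spr)
    }
  }
  truth <- do.call(rbind, truth)
  names(trees) <- truth$gene
  class(trees) <- "multiPhylo"
  attr(trees, "truth") <- truth
  trees
}

`%||%` <- function(x, y) if (is.null(x)) y else x
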