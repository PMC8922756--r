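## Synthetic alignments: HKY nucleotide simulation along a tree, and a
## codon-level simulator with omega-controlled acceptance thinning of
## nonsynonymous changes.

#' Rescale a tree to a given height
#'
#' Rescales all branch lengths so the maximum root-to-tip path equals
#' `height` (expected substitutions per site in the simulators); a
#' zero-length tree is returned unchanged.
#'
#' @param tree A `phylo` with branch lengths.
#' @param height Target height.
#' @return The rescaled `phylo`.
#' @export
scale_tree_height <- function(tree, height) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0) return(tree)
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(ape::Ntip(tree))])
  if (h > 0) tree$edge.length <- tree$edge.length * height / h
  tree
}

#' Simulate a nucleotide alignment along a tree
#'
#' Sequences evolve under an HKY-style model (transition/transversion ratio
#' `kappa`) whose stationary base frequencies are set so the expected GC
#' content equals `gc_target`. The tree is rescaled so its height equals
#' `subst_rate` expected substitutions per site.
#'
#' @param tree A `phylo` with branch lengths.
#' @param length Alignment length in bp (>= 30).
#' @param gc_target Target GC fraction, in (0, 1).
#' @param subst_rate Expected substitutions per site over the tree height;
#'   0 yields identical sequences (flagged `degenerate`).
#' @param seed Integer seed.
#' @param kappa Transition/transversion rate ratio.
#' @return A `gene_alignment`; attribute `degenerate = TRUE` when the tree
#'   carries no substitutions.
#' @export
simulate_alignment <- function(tree, length, gc_target, subst_rate, seed,
                               kappa = 2) {
  stopifnot(length >= 30L, gc_target > 0, gc_target < 1, subst_rate >= 0)
  tr <- scale_tree_height(tree, subst_rate)
  degenerate <- is.null(tr$edge.length) || sum(tr$edge.length) == 0 ||
    subst_rate == 0
  if (degenerate) tr$edge.length <- rep(0, nrow(tr$edge))
  bf <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2, (1 - gc_target) / 2)
  m <- with_seed(derive_seed(seed, "aln"), {
    ## root sequence with the exact target composition, so realized GC
    ## varies only through substitution drift, not root sampling
    n_gc <- round(length * gc_target)
    root <- sample(c(rep("c", n_gc %/% 2), rep("g", n_gc - n_gc %/% 2),
                     rep("a", (length - n_gc) %/% 2),
                     rep("t", length - n_gc - (length - n_gc) %/% 2)))
    dat <- phangorn::simSeq(tr, l = length, type = "DNA", bf = bf,
                            Q = c(1, kappa, 1, 1, kappa, 1), rootseq = root)
    toupper(as.character(dat))
  })
  out <- gene_alignment(m, gene_name = "sim")
  attr(out, "degenerate") <- degenerate
  out
}

## --- codon simulation ------------------------------------------------------

## One branch of codon evolution: `n_prop` proposed single-nucleotide
## changes at random codon positions; proposals creating stops are rejected;
## synonymous proposals accepted with prob min(1, 1/omega), nonsynonymous
## with prob min(1, omega), so the fixed nonsynonymous:synonymous rate ratio
## per respective opportunity is omega.
evolve_codons <- function(codons, n_prop, omega) {
  if (n_prop == 0L) return(codons)
  p_syn <- if (omega <= 0) 1 else min(1, 1 / omega)
  p_non <- min(1, omega)
  L <- length(codons)
  sites <- sample.int(L, n_prop, replace = TRUE)
  poss <- sample.int(3L, n_prop, replace = TRUE)
  u <- stats::runif(n_prop)
  for (k in seq_len(n_prop)) {
    cd <- codons[sites[k]]
    cur <- substr(cd, poss[k], poss[k])
    alt <- sample(setdiff(DNA_BASES, cur), 1L)
    nxt <- cd
    substr(nxt, poss[k], poss[k]) <- alt
    if (nxt %in% STOP_CODONS) next
    syn <- codon_aa(nxt) == codon_aa(cd)
    if (u[k] <= (if (syn) p_syn else p_non)) codons[sites[k]] <- nxt
  }
  codons
}

#' Simulate a codon alignment with a controlled dN/dS
#'
#' Substitutions are proposed uniformly per nucleotide site along each
#' branch; nonsynonymous proposals are thinned in proportion to `omega`
#' (and synonymous ones in proportion to `1/omega` when `omega > 1`), so
#' counting-method estimates recover the input ratio. No internal stop
#' codon is ever emitted.
#'
#' @param tree A `phylo` with branch lengths read as expected proposed
#'   substitutions per nucleotide site.
#' @param n_codons Number of codons (>= 50).
#' @param omega Target dN/dS (>= 0).
#' @param seed Integer seed.
#' @return A `gene_alignment` whose length is `3 * n_codons`.
#' @export
simulate_codon_alignment <- function(tree, n_codons, omega, seed) {
  stopifnot(n_codons >= 50L)
  if (omega < 0) stop("omega must be non-negative")
  tab <- codon_tables()
  with_seed(derive_seed(seed, "codons"), {
    root <- sample(tab$sense, n_codons, replace = TRUE)
    tr <- ape::reorder.phylo(tree, "postorder")
    n_nodes <- max(tr$edge)
    seqs <- vector("list", n_nodes)
    root_node <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
    seqs[[root_node]] <- root
    ## preorder traversal: parent before child
    ord <- rev(seq_len(nrow(tr$edge)))
    for (e in ord) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      b <- tr$edge.length[e]
      n_prop <- stats::rpois(1L, 3 * b * n_codons)
      seqs[[child]] <- evolve_codons(seqs[[par]], n_prop, omega)
    }
    m <- do.call(rbind, lapply(seq_len(ape::Ntip(tr)), function(i)
      str_chars(paste(seqs[[i]], collapse = ""))))
    rownames(m) <- tr$tip.label
    gene_alignment(m, gene_name = "sim_codon")
  })
}

#' Two-taxon codon alignment at a given divergence
#'
#' Convenience wrapper for estimator-recovery experiments: two sequences
#' separated by a total proposal rate of `divergence` substitutions per
#' nucleotide site.
#'
#' @param n_codons Number of codons.
#' @param omega Target dN/dS.
#' @param divergence Total expected proposed substitutions per site between
#'   the two sequences.
#' @param seed Integer seed.
#' @return A `gene_alignment` with rows `t1`, `t2`.
#' @export
simulate_codon_pair <- function(n_codons, omega, divergence = 0.4, seed = 1L) {
  tr <- ape::read.tree(text = sprintf("(t1:%f,t2:%f);",
                                      divergence / 2, divergence / 2))
  simulate_codon_alignment(tr, n_codons, omega, seed)
}
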