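test_that("distance models evaluate their closed forms", {
  sp <- simulate_species_tree(5, seed = 1)
  a <- simulate_alignment(sp, 400, 0.4, 0.1, seed = 2)
  dm_p <- distance_matrix(a, "p")
  expect_true(isSymmetric(unname(dm_p)))
  expect_true(all(diag(dm_p) == 0))
  ## JC69 at p = 0.1 equals the closed form
  m <- matrix("A", 3, 100, dimnames = list(c("x", "y", "z"), NULL))
  m["y", 1:10] <- "C"
  d <- distance_matrix(gene_alignment(m), "JC69")
  expect_equal(d["x", "y"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-6)
  ## identical rows: all distances zero
  m0 <- matrix("A", 3, 50, dimnames = list(c("x", "y", "z"), NULL))
  m0[, 1:25] <- "G"
  expect_true(all(distance_matrix(gene_alignment(m0), "JC69") == 0))
  ## p-distance equals the brute-force per-pair recount
  brute <- function(m, i, j) mean(m[i, ] != m[j, ])
  raw <- unclass(a)
  for (pr in list(c(1, 2), c(2, 4), c(3, 5)))
    expect_equal(dm_p[pr[1], pr[2]], brute(raw, pr[1], pr[2]))
})

test_that("saturated pairs are flagged infinite and block NJ with a message", {
  m <- matrix("A", 3, 40, dimnames = list(c("x", "y", "z"), NULL))
  m["y", ] <- rep(c("C", "G", "T", "A"), 10)[1:40]
  m["y", 37:40] <- "C"   # > 75% different from x
  dm <- distance_matrix(gene_alignment(m), "JC69")
  expect_true(is.infinite(dm["x", "y"]))
  expect_error(nj_tree(dm), "saturated|non-finite")
})

test_that("NJ recovers additive trees exactly", {
  tr <- tree_from_newick("((A:1,B:2):1,(C:3,D:4):1);")
  dm <- ape::cophenetic.phylo(tr)
  est <- nj_tree(dm[LETTERS[1:4], LETTERS[1:4]])
  expect_equal(rf_distance(est, ape::unroot(tr)), 0L)
  expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)
  ## taxon order must not change the unrooted topology
  perm <- c("D", "B", "A", "C")
  est2 <- nj_tree(dm[perm, perm])
  expect_equal(rf_distance(est2, est), 0L)
})

test_that("bootstrap supports are deterministic and high on clean signal", {
  sp <- simulate_species_tree(6, seed = 5)
  a <- simulate_alignment(sp, 3000, 0.4, 0.15, seed = 1)
  t1 <- bootstrap_supports(a, n_reps = 100, seed = 42)
  t2 <- bootstrap_supports(a, n_reps = 100, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))
  ## identical rows: star tree, no supports
  m <- matrix("A", 4, 60, dimnames = list(paste0("t", 1:4), NULL))
  star <- bootstrap_supports(gene_alignment(m), n_reps = 10, seed = 1)
  expect_equal(length(bipartitions(star)), 0L)
})

test_that("low-support collapsing contracts exactly the weak edges", {
  tr <- tree_from_newick("((A,B)90:1,(C,D)20:1,(E,F)50:1);")
  col <- collapse_low_support(tr, threshold = 33)
  expect_equal(length(bipartitions(col)), 2L)
  expect_false("A|B|E|F" %in% bipartitions(col))   # the CD split is gone
  ## all strong: unchanged; all weak: star
  keep <- collapse_low_support(tr, threshold = 10)
  expect_equal(rf_distance(keep, tr), 0L)
  star <- collapse_low_support(tr, threshold = 95)
  expect_equal(length(bipartitions(star)), 0L)
  expect_setequal(star$tip.label, tr$tip.label)
  ## single weak edge makes one polytomy of degree 4
  tr2 <- tree_from_newick("(((A,B)20:1,C):1,D,E);")
  col2 <- collapse_low_support(tr2, threshold = 33)
  expect_equal(length(bipartitions(tr2)) - length(bipartitions(col2)), 1L)
  ## probability scale
  trp <- tree_from_newick("((A,B)0.95:1,(C,D)0.2:1,(E,F)0.5:1);")
  colp <- collapse_low_support(trp, threshold = 33, scale = "probability")
  expect_equal(length(bipartitions(colp)), 2L)
  expect_error(collapse_low_support(ape::rtree(5), 33), "support")
})

test_that("collapsing never adds bipartitions and RF counts the removals", {
  for (s in 1:5) {
    sp <- simulate_species_tree(8, seed = s)
    a <- simulate_alignment(sp, 400, 0.4, 0.08, seed = s)
    tr <- bootstrap_supports(a, n_reps = 50, seed = s)
    col <- collapse_low_support(tr, threshold = 60)
    expect_true(all(bipartitions(col) %in% bipartitions(tr)))
    removed <- length(bipartitions(tr)) - length(bipartitions(col))
    expect_equal(rf_distance(tr, col), removed)
  }
})

test_that("RF distance matches phangorn on all pairs of 5-taxon topologies", {
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  expect_equal(length(trees), 15L)
  for (i in 1:14) for (j in (i + 1):15) {
    mine <- rf_distance(trees[[i]], trees[[j]])
    theirs <- as.integer(phangorn::RF.dist(trees[[i]], trees[[j]]))
    expect_identical(mine, theirs)
  }
  ## metric axioms on the same set
  for (i in 1:15) expect_identical(rf_distance(trees[[i]], trees[[i]]), 0L)
  for (i in 1:14) for (j in (i + 1):15) for (k in 1:15) {
    expect_lte(rf_distance(trees[[i]], trees[[j]]),
               rf_distance(trees[[i]], trees[[k]]) +
                 rf_distance(trees[[k]], trees[[j]]))
  }
})

test_that("RF on the two 4-taxon resolutions is 2, with normalization", {
  t1 <- tree_from_newick("((A,B),(C,D));")
  t2 <- tree_from_newick("((A,C),(B,D));")
  r <- rf_distance(t1, t2, normalized = TRUE)
  expect_equal(r$rf, 2L)
  expect_equal(r$normalized, 1)
  expect_error(rf_distance(t1, tree_from_newick("((A,B),(C,E));")), "prune")
})

test_that("NJ/JC69 converges on the generating topology as data grow", {
  hits <- c(short = 0, long = 0)
  for (s in 1:5) {
    sp <- simulate_species_tree(8, seed = 20 + s)
    for (len in c(short = 200, long = 5000)) {
      a <- simulate_alignment(sp, len, 0.4, 0.1, seed = s)
      est <- nj_tree(distance_matrix(a, "JC69"))
      nm <- names(which(c(short = 200, long = 5000) == len))
      if (rf_distance(est, ape::unroot(sp)) == 0L) hits[nm] <- hits[nm] + 1
    }
  }
  expect_gte(unname(hits["long"]), 4)
  expect_lte(hits["short"], hits["long"])
})

test_that("quartet scoring picks the majority resolution", {
  g <- c(replicate(2, tree_from_newick("((A,B),(C,D));"), simplify = FALSE),
         list(tree_from_newick("((A,C),(B,D));")))
  class(g) <- "multiPhylo"
  est <- estimate_species_tree(g, "exhaustive")
  expect_equal(rf_distance(est, g[[1]]), 0L)
  qs <- quartet_score(g[[1]], g)
  expect_equal(qs$score, 2L)
  expect_equal(qs$total_resolved, 3L)
  ## all gene trees identical: species tree equals them, every edge at 1
  sp <- simulate_species_tree(6, seed = 8)
  same <- simulate_gene_trees(sp, list(c(4, 0)), seed = 1)
  est2 <- estimate_species_tree(same, "exhaustive")
  expect_equal(rf_distance(est2, ape::unroot(sp)), 0L)
  fr <- suppressWarnings(as.numeric(est2$node.label))
  expect_true(all(fr[!is.na(fr)] == 1))
  expect_error(
    estimate_species_tree(simulate_gene_trees(
      simulate_species_tree(11, seed = 1), list(c(2, 0)), seed = 1),
      "exhaustive"),
    "9 taxa")
})

test_that("the exhaustive maximizer recovers mildly perturbed species trees", {
  hits <- 0L
  for (s in 1:8) {
    sp <- simulate_species_tree(7, seed = 50 + s)
    g <- simulate_gene_trees(sp, list(c(15, 1)), seed = s)
    est <- estimate_species_tree(g, "exhaustive")
    if (rf_distance(est, ape::unroot(sp)) == 0L) hits <- hits + 1L
    ## greedy search scores at least as well as the best gene tree
    greedy <- estimate_species_tree(g, "greedy-NNI")
    expect_gte(attr(greedy, "quartet_score"),
               max(vapply(g, function(t) quartet_score(t, g)$score, 0L)))
  }
  expect_gte(hits / 8, 0.75)
})
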