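test_that("the RF matrix is symmetric, zero-diagonal, and per-pair exact", {
  sp <- simulate_species_tree(8, seed = 1)
  g <- simulate_gene_trees(sp, list(c(6, 1)), seed = 2)
  dm <- tree_distance_matrix(g)
  expect_true(isSymmetric(unname(dm)))
  expect_true(all(diag(dm) == 0))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(dm[i, j], rf_distance(g[[i]], g[[j]]))
  same <- g[c(1, 1, 1)]
  names(same) <- paste0("c", 1:3)
  expect_true(all(tree_distance_matrix(same) == 0))
})

test_that("classical scaling reproduces Euclidean geometry to 1e-9", {
  set.seed(3)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("p", 1:5), NULL))
  dm <- as.matrix(dist(pts))
  emb <- pcoa_embed(dm)
  back <- as.matrix(dist(emb$coordinates))
  expect_lt(max(abs(back - dm)), 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 0))
  expect_lte(sum(emb$prop_variance), 1 + 1e-12)
  ## collinear points: a single informative axis
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  e3 <- pcoa_embed(d3)
  expect_equal(sum(e3$eigenvalues > 1e-9), 1L)
  x <- e3$coordinates[, 1]
  expect_equal(unname(abs(diff(sort(x)))), c(1, 1))
  ## all-zero distances: all coordinates zero
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(pcoa_embed(z)$coordinates == 0))
  expect_error(pcoa_embed(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("negative PCoA inertia is reported, not silently dropped", {
  sp <- simulate_species_tree(10, seed = 5)
  g <- simulate_gene_trees(sp, list(c(12, 2)), seed = 5)
  emb <- pcoa_embed(tree_distance_matrix(g))
  expect_gte(emb$negative_inertia, 0)
  expect_true(all(emb$eigenvalues > 0))
})

test_that("three planted regimes are recovered as three clusters", {
  suppressWarnings(requireNamespace("mclust", quietly = TRUE))
  sp <- simulate_species_tree(12, seed = 2)
  g <- simulate_gene_trees(sp, list(c(20, 0), c(20, 2), c(20, 6)),
                           seed = 2, mode = "anchored")
  truth <- attr(g, "truth")
  dm <- tree_distance_matrix(g)
  cl <- find_clusters(dm, 2:8)
  expect_equal(cl$k, 3L)
  expect_gte(mclust::adjustedRandIndex(cl$cluster[truth$gene], truth$regime),
             0.9)
  ## permuting input order only relabels clusters
  perm <- sample(length(g))
  cl2 <- find_clusters(tree_distance_matrix(g[perm]), 2:8)
  expect_equal(mclust::adjustedRandIndex(cl2$cluster[names(cl$cluster)],
                                         cl$cluster), 1)
  ## indistinguishable regimes do not force extra clusters
  g_same <- simulate_gene_trees(sp, list(c(15, 2), c(15, 2)), seed = 7,
                                mode = "independent")
  cl_same <- find_clusters(tree_distance_matrix(g_same), 2:6)
  expect_lt(max(cl_same$silhouette), 0.5)
  ## all-zero distances: one cluster with a warning
  same <- g[c(1, 1, 1, 1)]
  names(same) <- paste0("c", 1:4)
  expect_warning(cl0 <- find_clusters(tree_distance_matrix(same), 2:3),
                 "zero")
  expect_equal(cl0$k, 1L)
})

test_that("gene discordance is the 2-axis distance to the species tree", {
  sp <- simulate_species_tree(10, seed = 4)
  g <- simulate_gene_trees(sp, list(c(10, 1), c(10, 4)), seed = 4)
  space <- c(unclass(g), list(species = ape::unroot(sp)))
  class(space) <- "multiPhylo"
  emb <- pcoa_embed(tree_distance_matrix(space))
  gd <- gene_discordance(emb, "species")
  co <- emb$coordinates[, 1:2]
  for (nm in names(gd)) {
    expect_equal(gd[[nm]],
                 sqrt(sum((co[nm, ] - co["species", ])^2)))
  }
  ## a gene tree topologically identical to the species tree sits at gd 0
  g0 <- simulate_gene_trees(sp, list(c(5, 0)), seed = 1)
  space0 <- c(unclass(g0), list(species = ape::unroot(sp)))
  class(space0) <- "multiPhylo"
  gd0 <- suppressWarnings(
    gene_discordance(pcoa_embed(tree_distance_matrix(space0)), "species"))
  expect_true(all(gd0 < 1e-9))
  ## discordance rises with the SPR dose
  truth <- attr(g, "truth")
  expect_gt(mean(gd[truth$gene[truth$regime == 2]]),
            mean(gd[truth$gene[truth$regime == 1]]))
  expect_error(gene_discordance(emb, "absent"), "absent")
})

test_that("cluster property tests have type-I control and power", {
  set.seed(9)
  null_sig <- vapply(1:30, function(i) {
    props <- data.frame(cluster = rep(1:2, each = 10),
                        gc = rnorm(20, 0.38, 0.01))
    r <- cluster_property_report(props, "gc")
    !is.null(r$tests) && any(r$tests$p_value < 0.05)
  }, TRUE)
  expect_lte(mean(null_sig), 0.15)
  ## a +3 sigma shift is caught at the strongest star level
  props <- data.frame(cluster = rep(1:2, each = 15),
                      gc = c(rnorm(15, 0.38, 0.01), rnorm(15, 0.41, 0.01)))
  r <- cluster_property_report(props, "gc")
  expect_identical(r$tests$stars, "***")
  ## medians in the summary equal direct recomputation
  med <- r$summary$median[r$summary$cluster == 1]
  expect_equal(med, median(props$gc[props$cluster == 1]))
})

test_that("cluster concatenation ranks the faithful cluster nearest the truth", {
  sp <- simulate_species_tree(12, seed = 6)
  g <- simulate_gene_trees(sp, list(c(8, 0), c(8, 6)), seed = 6,
                           mode = "anchored")
  truth <- attr(g, "truth")
  alns <- lapply(seq_along(g), function(i)
    simulate_alignment(g[[i]], 600, 0.4, 0.1, seed = i))
  names(alns) <- truth$gene
  cl <- stats::setNames(truth$regime, truth$gene)
  out <- cluster_concatenate_and_retree(
    alns, cl, reference_trees = list(species = ape::unroot(sp)))
  rf1 <- out$rf$rf[out$rf$tree == "cluster1"]
  rf2 <- out$rf$rf[out$rf$tree == "cluster2"]
  expect_lt(rf1, rf2)
  ## a single cluster holding all genes equals the all-gene tree
  one <- cluster_concatenate_and_retree(alns, stats::setNames(
    rep(1L, length(alns)), names(alns)))
  expect_equal(rf_distance(one$trees$cluster1, one$trees$all), 0L)
  ## gene order inside a cluster does not change the topology
  sh <- sample(names(alns))
  two <- cluster_concatenate_and_retree(alns[sh], cl[sh])
  expect_equal(rf_distance(two$trees$cluster1, out$trees$cluster1), 0L)
  expect_error(cluster_concatenate_and_retree(alns[-1], cl), "missing")
})
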