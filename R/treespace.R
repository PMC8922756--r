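## The gene-tree landscape: Robinson-Foulds tree space, principal
## coordinates, cluster identification, the gene-tree discordance (GD)
## metric, and per-cluster property comparisons.

#' Pairwise Robinson-Foulds distance matrix over a set of trees
#'
#' Trees are pruned to their common tip set before comparison.
#'
#' @param trees Named `multiPhylo`/list of trees.
#' @return Symmetric integer matrix with zero diagonal, labelled by tree
#'   names.
#' @export
tree_distance_matrix <- function(trees) {
  k <- length(trees)
  stopifnot(k >= 2L)
  labels <- names(trees) %||% paste0("tree", seq_len(k))
  shared <- sort(Reduce(intersect, lapply(trees, `[[`, "tip.label")))
  if (length(shared) < 4L) stop("fewer than 4 tips shared by all trees")
  pruned <- lapply(trees, function(t)
    if (length(t$tip.label) > length(shared)) ape::keep.tip(t, shared) else t)
  bips <- lapply(pruned, bipartitions)
  d <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rf <- length(setdiff(bips[[i]], bips[[j]])) +
      length(setdiff(bips[[j]], bips[[i]]))
    d[i, j] <- d[j, i] <- as.integer(rf)
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling (double-centering of squared distances,
#' eigendecomposition, coordinates scaled by the square root of the
#' eigenvalue). Axes with non-positive eigenvalues are dropped and the
#' total dropped magnitude reported — RF spaces are generally
#' non-Euclidean, and the distortion is logged rather than corrected.
#'
#' @param dm Square symmetric distance matrix.
#' @return A `treespace_embedding`: list with `coordinates` (items x
#'   retained axes), `eigenvalues` (retained, descending),
#'   `prop_variance` (relative to the sum of positive eigenvalues) and
#'   `negative_inertia` (total magnitude of dropped negative eigenvalues).
#' @export
pcoa_embed <- function(dm) {
  dm <- as.matrix(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1L,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig, 0) * 1e-12 & eig > 0)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (!length(pos)) coords <- matrix(0, n, 1L, dimnames = list(rownames(dm), NULL))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig[pos],
    prop_variance = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(0),
    negative_inertia = sum(abs(eig[eig < 0]))),
    class = "treespace_embedding")
}

#' @export
print.treespace_embedding <- function(x, ...) {
  cat("<treespace_embedding> ", nrow(x$coordinates), " items, ",
      ncol(x$coordinates), " retained axes\n", sep = "")
  if (length(x$prop_variance))
    cat("  axis variance: ",
        paste(sprintf("%.1f%%", 100 * utils::head(x$prop_variance, 4L)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Identify clusters of gene trees in RF space
#'
#' Ward agglomerative clustering on the RF distance matrix with the number
#' of clusters chosen by maximum mean silhouette width over `k_range`
#' (smaller k wins ties). Labels in `exclude` (e.g. species-tree reference
#' points) are removed before clustering.
#'
#' @param dm Distance matrix from [tree_distance_matrix()].
#' @param k_range Candidate cluster counts (default `2:8`).
#' @param exclude Labels excluded from clustering.
#' @return A `cluster_assignment`: list with `cluster` (named integer
#'   vector), `k`, `silhouette` (mean width per candidate k) and
#'   `silhouette_width` (per item).
#' @export
find_clusters <- function(dm, k_range = 2:8, exclude = character(0)) {
  dm <- as.matrix(dm)
  keep <- setdiff(rownames(dm), exclude)
  dm <- dm[keep, keep]
  n <- nrow(dm)
  if (n < max(k_range) + 1L)
    k_range <- k_range[k_range <= n - 1L]
  if (all(dm == 0)) {
    warning("all tree distances are zero; returning a single cluster")
    cl <- stats::setNames(rep(1L, n), keep)
    return(structure(list(cluster = cl, k = 1L, silhouette = NULL,
                          silhouette_width = NULL, method = "ward.D2"),
                     class = "cluster_assignment"))
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
  sil_mean <- stats::setNames(numeric(length(k_range)), k_range)
  assignments <- list()
  widths <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(cl, dmatrix = dm)
    sil_mean[i] <- mean(sil[, "sil_width"])
    assignments[[i]] <- cl
    widths[[i]] <- sil[, "sil_width"]
  }
  best <- which.max(sil_mean)   # ties: first (smallest k)
  structure(list(cluster = assignments[[best]],
                 k = k_range[best],
                 silhouette = sil_mean,
                 silhouette_width = stats::setNames(widths[[best]], keep),
                 method = "ward.D2"),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k = ", x$k, " (",
      paste(table(x$cluster), collapse = "/"), " members)\n", sep = "")
  invisible(x)
}

#' Gene-tree discordance (GD)
#'
#' Euclidean distance between each gene tree and a reference tree (the
#' coalescent species tree) on the first two principal-coordinate axes
#' only.
#'
#' @param embedding A `treespace_embedding` containing `reference_label`.
#' @param reference_label Label of the reference tree in the embedding.
#' @return Named numeric vector of GD values (reference excluded).
#' @export
gene_discordance <- function(embedding, reference_label) {
  co <- embedding$coordinates
  if (!reference_label %in% rownames(co))
    stop("reference label '", reference_label, "' not present in the embedding")
  k <- min(2L, ncol(co))
  if (k < 2L)
    warning("fewer than 2 retained axes; GD computed on ", k, " axis")
  co <- co[, seq_len(k), drop = FALSE]
  ref <- co[reference_label, ]
  others <- setdiff(rownames(co), reference_label)
  gd <- sqrt(rowSums((co[others, , drop = FALSE] -
                        matrix(ref, length(others), k, byrow = TRUE))^2))
  stats::setNames(gd, others)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare gene properties between tree-space clusters
#'
#' Per-cluster medians and quartiles plus pairwise Welch t tests for each
#' property, with the usual star encoding (* < 0.05, ** < 0.01,
#' *** < 0.001). Singleton clusters are excluded from testing.
#'
#' @param props Data frame with a `cluster` column and numeric property
#'   columns.
#' @param properties Property column names (default: all numeric columns
#'   except `cluster`).
#' @return List with `summary` (cluster x property medians/quartiles) and
#'   `tests` (pairwise Welch results).
#' @export
cluster_property_report <- function(props, properties = NULL) {
  stopifnot("cluster" %in% names(props))
  if (is.null(properties))
    properties <- setdiff(names(props)[vapply(props, is.numeric, TRUE)], "cluster")
  cl <- props$cluster
  sizes <- table(cl)
  testable <- names(sizes)[sizes >= 2L]
  if (length(testable) < length(sizes))
    warning("singleton cluster(s) excluded from tests: ",
            paste(setdiff(names(sizes), testable), collapse = ", "))
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    do.call(rbind, lapply(properties, function(p) {
      v <- props[[p]][cl == k]
      data.frame(cluster = k, property = p, n = length(v),
                 q25 = stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE),
                 median = stats::median(v, na.rm = TRUE),
                 q75 = stats::quantile(v, 0.75, na.rm = TRUE, names = FALSE))
    }))
  }))
  tests <- list()
  if (length(testable) >= 2L) {
    pairs <- utils::combn(sort(testable), 2L)
    for (j in seq_len(ncol(pairs))) {
      k1 <- pairs[1L, j]; k2 <- pairs[2L, j]
      for (p in properties) {
        v1 <- props[[p]][cl == k1]; v2 <- props[[p]][cl == k2]
        if (sum(!is.na(v1)) < 2L || sum(!is.na(v2)) < 2L) next
        if (stats::var(v1, na.rm = TRUE) == 0 && stats::var(v2, na.rm = TRUE) == 0)
          next                        # both groups constant: nothing to test
        tt <- stats::t.test(v1, v2)   # Welch by default
        tests[[length(tests) + 1L]] <- data.frame(
          cluster_a = k1, cluster_b = k2, property = p,
          t = unname(tt$statistic), p_value = tt$p.value,
          stars = significance_stars(tt$p.value))
      }
    }
  }
  list(summary = summ,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Group-level rate comparison
#'
#' Welch t tests between groups of per-subject values (e.g. per-gene dN/dS
#' by functional group), with star encoding. Groups with fewer than two
#' values are excluded with a warning.
#'
#' @param values Named numeric vector (names = subjects).
#' @param grouping Named character vector mapping subject to group label.
#' @return List with `group_means` and `tests` (pairwise Welch results).
#' @export
group_rate_compare <- function(values, grouping) {
  g <- grouping[names(values)]
  if (anyNA(g)) stop("subjects missing from grouping: ",
                     paste(names(values)[is.na(g)], collapse = ", "))
  df <- data.frame(value = unname(values), group = unname(g))
  sizes <- table(df$group)
  drop <- names(sizes)[sizes < 2L]
  if (length(drop)) {
    warning("groups with n < 2 excluded: ", paste(drop, collapse = ", "))
    df <- df[!df$group %in% drop, ]
  }
  if (length(unique(df$group)) < 2L) stop("need >= 2 groups with n >= 2")
  means <- stats::aggregate(value ~ group, df, mean)
  pairs <- utils::combn(sort(unique(df$group)), 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- df$value[df$group == pairs[1L, j]]
    b <- df$value[df$group == pairs[2L, j]]
    tt <- stats::t.test(a, b)
    data.frame(group_a = pairs[1L, j], group_b = pairs[2L, j],
               t = unname(tt$statistic), p_value = tt$p.value,
               stars = significance_stars(tt$p.value))
  }))
  list(group_means = means, tests = tests)
}

#' Concatenate genes per cluster and re-infer one tree per cluster
#'
#' Genes are concatenated in sorted name order within each cluster and a
#' neighbor-joining tree is inferred from the concatenation; each cluster
#' tree's RF distance to any provided reference trees (e.g. the all-gene
#' concatenated tree and the species tree) is reported.
#'
#' @param alignments Named list of `gene_alignment`s (names = genes).
#' @param assignment A `cluster_assignment` (or named integer vector) over
#'   the gene names.
#' @param reference_trees Optional named list of trees for RF comparison.
#' @param model Distance model for inference.
#' @return List with `trees` (one per cluster, plus `all`) and `rf` (data
#'   frame of RF distances to each reference).
#' @export
cluster_concatenate_and_retree <- function(alignments, assignment,
                                           reference_trees = list(),
                                           model = "JC69") {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else assignment
  genes <- intersect(names(cl), names(alignments))
  if (length(genes) < length(cl))
    stop("alignments missing for: ",
         paste(setdiff(names(cl), names(alignments)), collapse = ", "))
  infer <- function(gs) {
    cat_aln <- concatenate_alignments(alignments[sort(gs)])
    ape::unroot(nj_tree(distance_matrix(cat_aln, model)))
  }
  ks <- sort(unique(cl))
  trees <- lapply(ks, function(k) infer(genes[cl[genes] == k]))
  names(trees) <- paste0("cluster", ks)
  trees$all <- infer(genes)
  rf <- NULL
  if (length(reference_trees)) {
    rf <- do.call(rbind, lapply(names(trees), function(tn) {
      do.call(rbind, lapply(names(reference_trees), function(rn) {
        pr <- prune_to_shared(trees[[tn]], reference_trees[[rn]])
        data.frame(tree = tn, reference = rn,
                   rf = rf_distance(pr[[1L]], pr[[2L]]))
      }))
    }))
  }
  list(trees = trees, rf = rf)
}
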