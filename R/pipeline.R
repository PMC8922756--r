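## End-to-end orchestration on synthetic data: one seed drives simulation,
## characterization, variability statistics, substitution rates, gene-tree
## inference and collapsing, concordance counting, and the tree-space
## analysis; every tabular output lands in `out_dir` and is checksummed in
## a manifest so reruns can be verified byte for byte.

#' Run the full synthetic analysis pipeline
#'
#' Generates a species tree, discordance-regime gene trees, per-gene
#' nucleotide and codon alignments and a small set of synthetic plastomes
#' (one carrying a gene deletion), then runs every analysis stage and
#' writes TSV outputs plus a checksum manifest. Deterministic under
#' `seed`.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory.
#' @param n_taxa Number of taxa in the species tree.
#' @param regimes List of `(n_genes, spr_moves)` discordance regimes.
#' @param gene_length Nucleotide alignment length per gene.
#' @param n_codons Codon-alignment length per gene for the rates stage.
#' @param omega Baseline dN/dS used for the codon simulations.
#' @param n_plastomes Number of synthetic plastomes (>= 2); the first one
#'   loses gene `"pg05"`.
#' @param bootstrap_reps Bootstrap replicates per gene tree.
#' @param collapse_threshold Bootstrap collapse threshold (percent).
#' @param window,step,pi_threshold Sliding-window parameters.
#' @return Invisibly, a list with each stage's in-memory results and the
#'   manifest data frame.
#' @export
run_synthetic_pipeline <- function(seed = 1L, out_dir = tempfile("pipeline"),
                                   n_taxa = 10L,
                                   regimes = list(c(n_genes = 8L, spr_moves = 0L),
                                                  c(n_genes = 8L, spr_moves = 2L)),
                                   gene_length = 800L, n_codons = 300L,
                                   omega = 0.2, n_plastomes = 3L,
                                   bootstrap_reps = 100L,
                                   collapse_threshold = 33,
                                   window = 600L, step = 100L,
                                   pi_threshold = 0.006) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  ## --- simulate -----------------------------------------------------------
  sp_tree <- simulate_species_tree(n_taxa, seed)
  gene_trees_true <- simulate_gene_trees(sp_tree, regimes, seed)
  truth <- attr(gene_trees_true, "truth")
  genes <- truth$gene
  alns <- lapply(seq_along(gene_trees_true), function(i)
    simulate_alignment(gene_trees_true[[i]], gene_length, gc_target = 0.37,
                       subst_rate = 0.08, seed = derive_seed(seed, "nt", i)))
  names(alns) <- genes
  codon_alns <- lapply(seq_along(gene_trees_true), function(i) {
    tr <- scale_tree_height(gene_trees_true[[i]], 0.15)
    simulate_codon_alignment(tr, n_codons, omega,
                             seed = derive_seed(seed, "cod", i))
  })
  names(codon_alns) <- genes
  plastomes <- lapply(seq_len(n_plastomes), function(i)
    simulate_plastome(plastome_config(
      seed = derive_seed(seed, "plast", i), id = sprintf("acc%02d", i),
      delete_gene = if (i == 1L) "pg05" else NULL)))
  emit(truth, "truth_gene_regimes.tsv")

  ## --- characterize -------------------------------------------------------
  structures <- lapply(plastomes, detect_quadripartite)
  jr <- junction_report(structures, plastomes)
  emit(jr, "junctions.tsv")
  pa <- presence_absence(plastomes)
  emit(pa$loss_events, "gene_losses.tsv")
  ssrs <- do.call(rbind, lapply(plastomes, function(r)
    find_ssrs(r$sequence, sequence_id = r$id)))
  emit(ssrs, "ssrs.tsv")

  ## --- gene statistics ----------------------------------------------------
  stats_tab <- gene_stats_table(alns)
  emit(stats_tab, "gene_stats.tsv")
  concat <- concatenate_alignments(alns[sort(genes)])
  profile <- sliding_window_pi(concat, window, step)
  emit(as.data.frame(profile), "window_pi.tsv")
  hotspots <- screen_hotspots(profile, pi_threshold)
  emit(hotspots, "hotspots.tsv")

  ## --- substitution rates -------------------------------------------------
  rates <- per_gene_dnds(codon_alns, reference_taxon = "t1")
  emit(rates, "gene_rates.tsv")

  ## --- gene trees ---------------------------------------------------------
  inferred <- lapply(seq_along(alns), function(i) {
    tr <- bootstrap_supports(alns[[i]], n_reps = bootstrap_reps,
                             seed = derive_seed(seed, "bs", i))
    if (!is.null(tr$node.label) && any(nzchar(tr$node.label)))
      collapse_low_support(tr, collapse_threshold) else tr
  })
  names(inferred) <- genes
  class(inferred) <- "multiPhylo"
  write_trees(inferred, file.path(out_dir, "gene_trees.nwk"))
  outputs <- c(outputs, file.path(out_dir, "gene_trees.nwk"))

  ## --- concordance --------------------------------------------------------
  conc <- summarize_concordance(sp_tree, inferred)
  emit(as.data.frame(conc), "concordance.tsv")

  ## --- tree space ---------------------------------------------------------
  space_trees <- c(unclass(inferred), list(species = ape::unroot(sp_tree)))
  class(space_trees) <- "multiPhylo"
  dm <- tree_distance_matrix(space_trees)
  emb <- pcoa_embed(dm)
  emit(data.frame(label = rownames(emb$coordinates),
                  emb$coordinates[, seq_len(min(3L, ncol(emb$coordinates))),
                                  drop = FALSE]),
       "embedding.tsv")
  clusters <- find_clusters(dm, k_range = 2:min(6L, length(genes) - 2L),
                            exclude = "species")
  gd <- gene_discordance(emb, "species")
  props <- merge(stats_tab,
                 data.frame(gene = names(clusters$cluster),
                            cluster = unname(clusters$cluster)), by = "gene")
  props <- merge(props, rates[, c("gene", "omega")], by = "gene")
  props$gd <- gd[props$gene]
  emit(props, "gene_properties.tsv")
  report <- cluster_property_report(props,
                                    properties = c("gc", "aligned_length", "PV"))
  emit(report$summary, "cluster_summary.tsv")
  if (!is.null(report$tests)) emit(report$tests, "cluster_tests.tsv")

  ## --- manifest -----------------------------------------------------------
  manifest <- data.frame(seed = seed, file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(species_tree = sp_tree, gene_trees_true = gene_trees_true,
                 alignments = alns, plastomes = plastomes,
                 inferred_trees = inferred, concordance = conc,
                 distance_matrix = dm, embedding = emb, clusters = clusters,
                 gd = gd, properties = props, manifest = manifest,
                 out_dir = out_dir))
}
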