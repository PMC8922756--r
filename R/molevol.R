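## Taxon- and gene-level substitution-rate summaries built on the NG86
## pairwise estimator: rates of every taxon against a designated reference
## on the concatenated common protein-coding genes, per-gene rates averaged
## over taxa, and the dN floor used to exclude near-invariant genes from
## omega comparisons.

#' Per-taxon dN/dS against a reference taxon
#'
#' Genes are restricted to those shared by all taxa, concatenated in sorted
#' gene-name order, and each non-reference taxon is compared with the
#' reference by [ng86_pair()].
#'
#' @param alignments Named list of codon `gene_alignment`s.
#' @param reference_taxon Taxon id present in every alignment.
#' @return Data frame `(taxon, dN, dS, omega)`; the reference compared with
#'   itself would be (0, 0, NA) and is excluded.
#' @export
pairwise_dnds_vs_reference <- function(alignments, reference_taxon) {
  for (g in names(alignments)) {
    if (!reference_taxon %in% aln_taxa(alignments[[g]]))
      stop("reference taxon '", reference_taxon,
           "' missing from gene '", g, "'")
  }
  shared <- Reduce(intersect, lapply(alignments, aln_taxa))
  cat_aln <- concatenate_alignments(alignments[sort(names(alignments))])
  seqs <- aln_sequences(cat_aln)
  others <- setdiff(shared, reference_taxon)
  rows <- lapply(others, function(tx) {
    r <- ng86_pair(seqs[[reference_taxon]], seqs[[tx]])
    data.frame(taxon = tx, dN = r$dN, dS = r$dS, omega = r$omega)
  })
  do.call(rbind, rows)
}

#' Per-gene dN/dS (mean over taxa against the reference)
#'
#' For every gene, dN and dS are averaged over all non-reference taxa
#' compared with the reference; omega is the ratio of the mean rates.
#' Genes whose mean dN falls below `dn_floor` are flagged for exclusion
#' from omega comparisons (near-invariant genes yield unstable ratios).
#'
#' @param alignments Named list of codon `gene_alignment`s.
#' @param reference_taxon Taxon id present in every alignment.
#' @param dn_floor Minimum mean dN for a gene to enter omega plots
#'   (default 0.0003).
#' @return Data frame `(gene, dN, dS, omega, low_dn)`.
#' @export
per_gene_dnds <- function(alignments, reference_taxon, dn_floor = 3e-4) {
  rows <- lapply(names(alignments), function(g) {
    a <- alignments[[g]]
    if (!reference_taxon %in% aln_taxa(a))
      stop("reference taxon '", reference_taxon, "' missing from gene '", g, "'")
    seqs <- aln_sequences(a)
    others <- setdiff(aln_taxa(a), reference_taxon)
    prs <- lapply(others, function(tx) ng86_pair(seqs[[reference_taxon]], seqs[[tx]]))
    dn <- mean(vapply(prs, `[[`, 0, "dN"), na.rm = TRUE)
    ds <- mean(vapply(prs, `[[`, 0, "dS"), na.rm = TRUE)
    data.frame(gene = g, dN = dn, dS = ds,
               omega = if (!is.na(ds) && ds > 0) dn / ds else NA_real_,
               low_dn = !is.na(dn) && dn < dn_floor)
  })
  do.call(rbind, rows)
}
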