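# plastidscape

Comparative plastome analysis and the landscape of plastid gene trees,
in R.

Plastid genomes are usually analyzed as one concatenated locus, but the
~80 protein-coding genes (PCGs) they carry can support conflicting
topologies. `plastidscape` is for phylogeneticists who want to measure
that conflict rather than average over it. It covers three layers:

* **Plastome characterization** — GenBank flat-file reading, exact
  inverted-repeat (IR) detection and quadripartite partitioning
  (LSC/IRb/SSC/IRa), IR junction reports, gene presence/absence across
  accessions, sliding-window nucleotide diversity (π, 600 bp windows /
  100 bp steps by default) with hotspot screening (π > 0.006), and
  perfect-SSR scanning with the standard class minima
  (≥10/5/4/3/3/3 units for 1–6 bp motifs).
* **Substitution rates** — Nei–Gojobori (1986) counting estimates of
  dN, dS and ω = dN/dS with pathway averaging and Jukes–Cantor
  correction, per gene and per taxon against a reference, plus Welch-t
  comparisons between functional groups (stars at 0.05/0.01/0.001).
* **Gene-tree landscape** — NJ gene trees with bootstrap and
  low-support collapsing (default < 33%), Robinson–Foulds tree space
  with principal coordinates, Ward/silhouette cluster identification,
  a per-gene discordance score GD (distance to the species tree on the
  first two PCoA axes), PhyParts-style per-edge concordance counts, and
  a quartet-support species-tree estimator. Externally inferred newick
  trees drop straight in.

A first-class synthetic-data module generates species trees,
discordance-regime gene trees, nucleotide/codon alignments with
controlled GC, rate and ω, and whole annotated plastomes with planted
IRs, SSRs and gene losses — with machine-readable ground truth — so the
entire pipeline is testable offline.

## Core quantities

For an alignment with rows *i*, *j* compared at their mutually ungapped
sites, π is the mean over pairs of (differences / compared sites);
S counts columns with ≥ 2 determinate states and PV = S / aligned
length. NG86 rates are dN = JC(N_d / N_s) and dS = JC(S_d / S_s), with
per-codon site counts split over non-stop single-nucleotide changes and
multi-hit codons averaged over stop-free mutational pathways;
JC(p) = −(3/4)·ln(1 − 4p/3). The RF distance is the symmetric
difference of non-trivial bipartitions; tree space is classical scaling
of the RF matrix; GD(g) = ‖x(g) − x(species)‖ on axes 1–2.

## Worked example

```r
library(plastidscape)

## three discordance regimes around one species tree
sp    <- simulate_species_tree(12, seed = 1)
genes <- simulate_gene_trees(sp, list(c(n_genes = 20, spr_moves = 0),
                                      c(n_genes = 20, spr_moves = 2),
                                      c(n_genes = 20, spr_moves = 6)),
                             seed = 1, mode = "anchored")

space <- c(unclass(genes), list(species = ape::unroot(sp)))
class(space) <- "multiPhylo"
dm  <- tree_distance_matrix(space)
emb <- pcoa_embed(dm)
emb
#> <treespace_embedding> 61 items, 10 retained axes
#>   axis variance: 81.2%, 17.3%, 0.3%, 0.3%

find_clusters(dm, 2:8, exclude = "species")
#> <cluster_assignment> k = 3 (20/20/20 members)

gd <- gene_discordance(emb, "species")
round(tapply(gd, attr(genes, "truth")$regime, mean), 2)
#>     1     2     3
#>  0.34  7.86 15.99
```

The embedding keeps 10 informative axes, with the first two carrying
98.5% of the retained inertia; silhouette-selected clustering recovers
the three planted regimes exactly, and mean GD rises with the planted
SPR dose (0.34 → 7.86 → 15.99 RF-scale units), i.e. the discordance
score orders the regimes correctly.

```r
## a synthetic plastome with planted structure
rec <- simulate_plastome(plastome_config(seed = 1))
detect_quadripartite(rec)
#> <quadripartite_structure> IR length 5000 bp
#>   LSC [0,24000)  IRb [24000,29000)  SSC [29000,37000)  IRa [37000,42000)

find_ssrs(rec$sequence, sequence_id = rec$id)
#>   sequence_id motif motif_length unit_count start  end
#> 1 synplastome     A            1         12   500  512
#> 2 synplastome    AT            2          8  1500 1516
#> 3 synplastome  AGAT            4          4  2500 2516

## omega recovery by the NG86 counting estimator
p <- aln_sequences(simulate_codon_pair(2000, omega = 0.2, seed = 1))
r <- ng86_pair(p[[1]], p[[2]])
sprintf("dN = %.4f  dS = %.4f  omega = %.3f", r$dN, r$dS, r$omega)
#> "dN = 0.0840  dS = 0.3874  omega = 0.217"
```

The detected IR boundaries equal the planted ones exactly, the three
planted SSRs (and nothing else) are reported at their exact positions,
and a 2,000-codon pair simulated at ω = 0.2 is estimated at 0.217.

`run_synthetic_pipeline(seed, out_dir)` chains every stage —
simulation, characterization, gene statistics, rates, tree inference
and collapsing, concordance, tree space — and writes TSV reports plus
an md5 manifest; the same seed reproduces every output byte for byte.

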