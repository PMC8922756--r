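---
title: "Plastome variability and the plastid gene-tree landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome variability and the plastid gene-tree landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidscape)
```

# The problem

Plastid genomes are routinely treated as a single linked locus, yet the
individual protein-coding genes (PCGs) they carry often tell different
phylogenetic stories. `plastidscape` implements a complete desk-scale
workflow for asking *how much* they disagree and *which genes disagree
in the same way*:

1. **Characterization** — quadripartite structure (LSC + IRb + SSC + IRa),
   IR junction shifts, sliding-window nucleotide diversity with hotspot
   screening, perfect-microsatellite (SSR) content, and gene
   presence/absence across accessions.
2. **Molecular evolution** — Nei–Gojobori (1986) counting estimates of
   dN, dS and ω per gene and per taxon against a reference, with
   Welch-t comparisons between functional groups.
3. **Gene-tree landscape** — per-gene trees (built in, or imported from
   external ML/BI engines), bootstrap collapsing, a Robinson–Foulds (RF)
   tree space with principal coordinates, cluster identification, a
   per-gene discordance score (GD), per-edge concordance counting, and a
   quartet-support species-tree estimator.

Every stage is driven by a synthetic-data module that plants known
structure (IR boundaries, SSR motifs, gene losses, discordance regimes,
ω values), so the whole pipeline is testable without downloading a
single accession.

# Models and estimators

## Sliding-window nucleotide diversity

π is the mean proportion of differing sites over all unordered sequence
pairs, with *pairwise deletion*: a column is dropped only for the pairs
in which either sequence has a gap or N. This matches the per-pair site
handling of the standard population-genetics tools and keeps short or
gappy genes usable. Windows default to **600 bp advanced by 100 bp**, and
hotspot screening keeps maximal runs of windows with π strictly above
**0.006** — the customary screening setup for plastome variability scans.
`PV = S / aligned length` uses the full aligned length (gap columns
included) as denominator; this is deliberate and documented, since "gene
length" in the screening literature refers to the alignment.

## SSR scanning

`find_ssrs()` reports maximal perfect tandem repeats of primitive
(non-periodic) motifs of 1–6 bp with class minima of ≥10, 5, 4, 3, 3, 3
units for mono- through hexanucleotides. Motifs are canonicalized to
their lexicographically smallest rotation; a run of a periodic motif is
reported once under its shortest period; overlaps between motif classes
are resolved greedily, longest run first. Scanning a reverse complement
yields the same number of records.

## Inverted-repeat detection

Plastome IRs are exact repeats, so detection is exact-match
seed-and-extend: 31-mers sampled every `min_ir_len/2` positions are
looked up in the reverse complement and extended blockwise. The longest
pair of disjoint reverse-complement copies of at least `min_ir_len`
(default 1,000 bp) defines IRb/IRa; the shorter enclosed single-copy
region is labelled SSC. The detector works on the linear coordinates of
the record and assumes the IR does not span the sequence origin — the
convention plastome assemblies follow by starting in the LSC. Junction
reports give the signed distance from each of the four junctions
(JLB, JSB, JSA, JLA) to the nearest annotated feature edge, negative
inside the IR, with the overlap length when a junction falls inside a
gene.

## Nei–Gojobori dN/dS

`ng86_pair()` is a from-scratch implementation of the 1986 counting
method. Per-codon synonymous site counts split each codon position over
its single-nucleotide alternatives *that do not create a stop codon*, so
N_sites + S_sites = 3 per compared codon while stop pathways are
excluded. Codon pairs differing at 2–3 positions are averaged over all
orderings of the changes, discarding orderings that pass through a stop
(falling back to all orderings in the rare case every one is blocked).
Proportions are corrected with Jukes–Cantor,
d = −(3/4)·log(1 − 4p/3), reported as saturated when p ≥ 3/4.
A counting method is deterministic and dependency-free; it is *not* a
likelihood fit, and we claim rank-level agreement (orderings,
above/below-1 classification), not equality with codeml's branch
estimates. Genes whose mean dN falls below **0.0003** are flagged and
excluded from ω comparisons, because the ratio is unstable when the
numerator is essentially zero.

## Gene trees and RF tree space

The built-in inference route is neighbor joining on p/JC69/K2P distances
with nonparametric bootstrap (default 1,000 column resamples); supports
below **33%** are collapsed into polytomies before any topology-based
summary, reflecting uncertainty rather than resolving it arbitrarily.
External newick gene trees with supports are first-class inputs.

RF distances are computed on canonical non-trivial bipartitions of the
unrooted topologies. The tree space is the classical-scaling (PCoA)
embedding of the pairwise RF matrix; negative-eigenvalue axes (RF spaces
are generally non-Euclidean) are dropped and their total magnitude is
reported as `negative_inertia` rather than corrected away, so users can
judge the distortion. Gene-tree discordance is

GD(g) = Euclidean distance between gene *g* and the species tree on the
first two principal coordinates,

exactly two axes, even when more are retained — GD is a display-space
quantity and is interpreted as such.

Clusters are found by Ward agglomeration (`ward.D2`) on the RF matrix
with k selected by maximum mean silhouette over 2–8; k is never
hard-coded: a three-cluster structure, when reported, is a *result*.
Species trees are embedded as points but excluded from clustering.

## Concordance counting

For every internal edge of the species tree, each gene tree is
classified as concordant (the edge's bipartition, restricted to shared
tips, occurs in the gene tree), conflicting (some supported gene
bipartition on the shared tips is incompatible with it), or
uninformative (trivial restriction or unresolved gene tree); the modal
conflicting bipartition is reported as the top alternative. When a gene
conflicts through several bipartitions, the one with the smallest
smaller side is recorded (canonical string order breaking ties) — a
deterministic convention, since the classic tools do not document
theirs. The four per-edge counts always sum to the number of gene trees.
A `support_cutoff` (off by default) silences gene-tree edges below a
support threshold, mimicking the "no bootstrap support" category of
published concordance pies.

## Quartet-support species trees

`estimate_species_tree()` maximizes the number of gene-tree quartets
agreeing with the candidate topology — exhaustively over all unrooted
topologies up to 9 taxa, by greedy NNI hill-climbing above that. Each
internal edge is annotated with the fraction of resolved gene quartets
straddling the edge that agree with it. This is a transparent
quartet-support fraction in the spirit of coalescent summary methods; it
is not a local posterior probability and is never labelled as one.

# The synthetic-data generator

The generator's defaults are the package's study conditions; they are
chosen once and stated here.

**Species trees** are pure-birth (Yule) trees — the simplest null with no
rate structure to confound discordance — with tips `t1..tN`.

**Discordance regimes.** Two modes, because two different questions are
asked of the data:

* `independent` (default): every gene tree receives its own independent
  draw of `spr_moves` subtree-prune-regraft moves from the species tree.
  This gives direct control of the *distance to the species tree* (0
  moves ⇒ RF 0; distributions for different doses separate cleanly) and
  is the right null for discordance-rate and concordance-count
  questions. It deliberately does **not** create clusters: independent
  perturbations scatter isotropically, so within-regime distances exceed
  between-regime distances.
* `anchored`: each regime first draws one anchor topology (the species
  tree plus `spr_moves` SPR moves, redrawn until the anchor realizes at
  least one changed bipartition per move, RF ≥ 2·`spr_moves`), and genes
  jitter around the anchor by a single NNI with probability 0.25 plus
  multiplicative branch-length noise. Regimes then form compact,
  well-separated clusters — the structure that real plastid data show
  when groups of genes share a conflicting signal, and the structure the
  cluster-recovery analysis presumes. The jitter probability is kept
  small so the within-regime diameter (≤ 2 NNI ⇒ RF ≤ 4) stays well
  below the anchor spacing.

**Alignments** evolve under an HKY-style model (κ = 2) whose stationary
frequencies hit the target GC; the root sequence is drawn with the exact
target composition so realized GC varies only through substitution
drift (within ±0.03 of target at 1,000 bp). The tree is rescaled so its
height equals the requested substitutions per site.

**Codon alignments** use proposal–acceptance thinning: substitutions are
proposed uniformly per site, proposals creating stops are rejected, and
nonsynonymous proposals are accepted with probability min(1, ω)
(synonymous with min(1, 1/ω) when ω > 1). This reproduces the *ratio*
NG86 measures without a full codon rate matrix; recovery is within a few
percent at ω ∈ {0.1, 0.5, 1} for 5,000-codon pairs at 0.4
proposals/site divergence.

**Plastomes** are assembled as LSC + IRb + SSC + IRa with IRa the exact
reverse complement of IRb; protein-coding genes (stop-free ORFs) are
placed on random strands in all segments, with genes that cannot fit the
IR moved to the LSC. Ground truth for every planted object — region
boundaries, gene coordinates and strands, SSR positions, deletions — is
attached to the record and exportable as TSV. Two generator guarantees
matter for exactness tests: incidental SSRs in the random backbone are
scrubbed, so the planted motifs are exactly the reportable set (planted
positions live in a reserved gene-free LSC prefix); and the SSC's
flanking bases are patched when they would extend the exact repeat by
chance, so detected IR boundaries equal the planted ones bit for bit.

What the generator does **not** emulate: indels and alignment error,
among-site rate heterogeneity, base-composition heterogeneity across the
genome, imperfect/compound SSRs, and coalescent branch-length signatures
of incomplete lineage sorting. Tests passing on these data therefore
demonstrate correctness of the estimators and the recovery of planted
structure under clean conditions — not robustness to the noise sources
of real assemblies.

# Numerical choices

* One integer seed drives everything; per-stage streams are derived by a
  stable integer hash (`derive_seed`), so stages are independently
  reproducible and inserting a stage does not reshuffle the others.
* NJ ties and hclust behaviour follow ape/stats defaults;
  determinism is guaranteed by the seeded streams.
* Silhouette k-selection breaks ties toward the smaller k; an all-zero
  distance matrix short-circuits to a single cluster with a warning.
* Saturated distances (p ≥ 3/4 under JC69) are flagged `Inf` and refuse
  NJ rather than silently truncating.
* Welch t-tests are skipped (not zero-filled) when both groups are
  constant or a group has n < 2; stars follow the 0.05/0.01/0.001
  convention.
* Bootstrap supports are integer percentages; collapsing uses strict
  `<` so an edge exactly at the threshold survives.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes a laptop handles in minutes: tree-space recovery uses
three regimes × 20 genes on 12 taxa over 20 replicate seeds; ω recovery
uses two-taxon 5,000-codon alignments over 20 seeds per ω; structural
recovery uses plastomes of 42–110 kb with IRs of 1–25 kb. These sizes
were chosen to make the Monte-Carlo success criteria (rates over 20
replicates) stable while keeping the full suite fast.

# Known limitations

* The GenBank reader covers the flat-file subset plastome records use
  (CDS/tRNA/rRNA, `join`, `complement`, origin-spanning joins,
  `/gene=` qualifiers); it is not a general GenBank parser, and
  ambiguity codes other than N are rejected by design.
* The IR detector requires exact repeats; diverged (approximate) IRs
  are reported at their longest exact core.
* The quartet estimator's exhaustive mode is factorially bounded
  (≤ 9 taxa); the greedy mode inherits the usual local-optimum caveat.
* NG86 averages pairs against one reference taxon; it is a screening
  statistic, not a substitute for branch-model likelihood estimates.
* GD depends on the embedding: it is comparable between genes within
  one tree space, not across spaces.
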