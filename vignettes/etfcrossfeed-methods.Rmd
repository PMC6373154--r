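---
title: "Methods: Etf gene-cluster mining, reaction-context phylogenetics, and fermentation carbon balances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Etf gene-cluster mining, reaction-context phylogenetics, and fermentation carbon balances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etfcrossfeed)
```

## What this package models

Anaerobic cross-feeding of lactate — lactate and acetate produced by some
bacteria being converted to butyrate by others — rests on flavin-based
electron bifurcation. Two electron-transferring flavoprotein (EtfAB)
complexes do the coupling: an FAD-dependent lactate dehydrogenase complex
(2 NAD⁺ + Fd_red + lactate → 2 NADH + Fd_ox + pyruvate) and the
butyryl-CoA dehydrogenase complex (2 NADH + Fd_ox + crotonyl-CoA →
2 NAD⁺ + Fd_red + butyryl-CoA). The package implements two computational
arms around this biology:

1. **Comparative genomics and phylogenetics.** Locate *etfA*/*etfB* gene
   pairs in annotated genomes, classify each pair's neighbourhood
   (lactate-oxidation versus butyrate-formation markers), align the protein
   sets, and ask whether the complexes cluster on a tree by catalysed
   reaction rather than by species.
2. **Fermentation accounting.** Convert batch before/after concentration
   measurements into a carbon balance in mmol C, quantify the unaccounted
   residual X (biomass plus fermentation gases), and verify that the
   implied net stoichiometry is realisable as a nonnegative flux through an
   electron-bifurcating reaction network with all cofactor pools closed.

A third, first-class component generates every input synthetically —
annotated replicons with planted clusters, protein families evolved along
known trees, concentration tables from known fluxes — so the entire
pipeline is testable offline against known ground truth.

## Genome mining

Annotations are read from GenBank flat files or GFF3 + FASTA into a tibble
of coding genes. Coordinates are 1-based inclusive throughout, the
R/Bioconductor (and GenBank) convention; no second internal coordinate
system is maintained. Reverse-strand proteins are translated in
reading-frame direction.

Homology calls use Smith–Waterman local alignment with BLOSUM62 and the
classic protein-search gap costs (open 11, extend 1, a gap of length
L costing `open + L * extend`). Because no acceptance threshold is part of
the published search protocol, the defaults are deliberately permissive
twilight-zone values — identity ≥ 0.25 over aligned columns and query
coverage ≥ 0.5 — and both are arguments.

An *etfA*/*etfB* pair is called when hits for the two subunits lie on the
same replicon with at most one intervening gene (strand unconstrained; the
published cluster diagrams include head-to-head layouts). The context label
comes from marker hits within ±5 coding genes (configurable):

* lactate markers (LldP permease, GlcD-like FAD oxidoreductase) *and*
  butyrate markers present → `ambiguous`, flagged rather than guessed;
* LldP + GlcD → `LldP_GlcD`; GlcD alone → `GlcD`. LldP alone stays
  `unassigned`: a permease without the oxidoreductase is weak evidence of
  an oxidation context, and the label set has no permease-only class;
* 3-hydroxybutyryl-CoA dehydrogenase dominates acyl-CoA dehydrogenase, so
  a neighbourhood with both is `3-hydroxybutyryl-CoA`;
* no marker in the window → `unassigned`.

Etf hits that cannot be paired are reported in a side table, never as
clusters; likewise a marker-only locus (a GlcD-like gene with no *etf*
pair) is visible in the hit tables but never counted as a cluster.

## Alignment

`align_pair()` and `progressive_align()` implement a ClustalW-style
aligner: the substitution matrix defaults to the literal identity matrix
(match 1, mismatch 0) with affine penalties open 8, extend 0.1, kept
fractional and real-valued. The guide tree is UPGMA on a quick 3-mer
distance, `1 − shared 3-mers / (min length − 2)` with multiset counting;
profiles are merged in guide-tree order under average-of-pairs scoring
(gap symbols contribute zero). Dynamic-programming ties are broken
diagonal > vertical > horizontal, so outputs are bit-stable. This
reproduces the *kind* of alignment the published analysis used; matching a
specific GUI tool's output column-for-column is a non-goal — downstream
claims are made at the level of tree topology and support, which is what
the tests check.

## Distances, UPGMA, bootstrap

The mismatch fraction p is computed with pairwise deletion (per-pair
ungapped sites; `complete` deletion is available), then corrected with a
20-state equal-rates (Jukes–Cantor type) model generalised to proteins:

d = −(19/20) · ln(1 − (20/19) · p),

capped at 10 substitutions/site near saturation (p ≥ 19/20) with a
warning. UPGMA uses size-weighted average linkage with node height equal
to half the merge distance; ties take the smallest (row, column) pair in
current label order — determinism is preferred over fidelity to any
particular tool's tie behaviour. The result is rooted and ultrametric to
1e−9 by construction.

Bootstrap support resamples alignment columns with replacement to the
original length; replicate r reseeds the generator at `seed + r` so
partial runs are reproducible. Support for an internal node is the
percentage of replicate trees containing the *identical rooted tip set*.
The conventional 30% display threshold annotates nodes rather than
collapsing them, so clade queries keep working on the full topology; the
root is reported as `NA` (it is trivially present in every replicate).

## The separation question

`separation_report()` joins neighbourhood contexts to tree tips, maps
contexts to two reaction groups (`GlcD`/`LldP_GlcD` → lactate;
`3-hydroxybutyryl-CoA`/`acyl-CoA` → butyrate, configurable), and reports
for each group: rooted monophyly, the supporting node's bootstrap value,
and — when monophyly fails — the intruding tips under the group's MRCA
("breakers", the published trees show two such outgroup-forming tips).
Monophyly is evaluated on the rooted UPGMA tree; no unrooted relaxation is
applied, matching the tree type the claim was made on.
`cross_species_similarity()` quantifies the complementary claim directly
on the distance matrix: the mean distance between same-context,
different-species pairs should be smaller than between same-species,
different-context pairs when the paralog split predates speciation.

## Carbon and electron balances

Concentrations convert to mmol C through fixed molar masses (sodium
lactate 112.06 g/mol, sodium acetate 82.03, the free acids 90.08/60.05/
88.11/74.08, ethanol 46.07) and carbon counts; the registry also stores
degrees of reduction (γ = 4C + H − 2O per molecule: lactate 12, acetate 8,
butyrate 20, ethanol 12, pyruvate 10, H₂ 2) with NADH and reduced
ferredoxin carrying 2 electrons. For acyl-CoA thioesters only the acyl
moiety is counted and coenzyme A is a neutral carrier, which makes every
shipped reaction balance exactly in both carbon and electrons.

`carbon_balance()` nets after − before per metabolite. Inertness
assumptions (the yeast-extract-derived butyrate and propionate pools) are
applied by subtracting the initial pool from both phases. X is defined as
consumed C − produced C, so carbon conservation holds identically; a
negative X is reported and flagged, never hidden. Utilization is
100 · consumed/initial per substrate: the standard batch table yields 98%
for lactate.

`round_balance()` rounds nets to a 10 mmol C granularity for display and
records every metabolite whose value rounding changed. This is deliberate:
the published simplified equation prints acetate as −100 where the
arithmetic net is −94 (rounding to −90); the discrepancy surfaces in the
diagnostics table instead of being silently reproduced.

## The reaction network and flux fitting

The default network contains the two bifurcating Etf reactions, pyruvate:
ferredoxin oxidoreductase (the clostridial norm for pyruvate → acetyl-CoA;
the source text only says pyruvate is oxidised), thiolase, 3-hydroxy-
butyryl-CoA dehydrogenase and crotonase, both butyrate-release routes
(phosphotransbutyrylase/butyrate kinase and butyryl-CoA:acetate
CoA-transferase), acetate kinase in both directions, the acetaldehyde/
alcohol dehydrogenase ethanol route, a ferredoxin hydrogenase, a
ferredoxin:NAD⁺ oxidoreductase, and a chemiosmotically coupled ATP
synthase/hydrolase pair — ion-gradient bookkeeping itself is out of scope,
so the pair simply lets the adenine nucleotide pool close at a defensible
place. Biomass is a pseudo-species drawn from acetyl-CoA (2 C per unit)
whose electron content is adjustable through a reversible exchange with
the NAD pool (`biomass_e`), implementing the idea that the residual X has
free carbon and electron composition within what the balance allows.

`fit_flux()` solves for nonnegative rates v with S·v matching the target
net production of the constrained exchange species while internal species
and cofactor pools are exactly closed (CO₂, H₂, H₂O, biomass are free
unless constrained). The solver is nonnegative least squares
(`pracma::lsqnonneg`) on closure rows weighted 100:1 with a 1e−3 ridge —
the network contains antiparallel reaction pairs, so the plain problem is
rank-deficient — followed by an unconstrained SVD polish on the active
set, which brings residuals to machine precision for feasible targets.
Infeasible targets (e.g. butyrate demanded with no carbon source) return a
certificate naming the species that cannot be closed or matched.

## What the generators emulate — and what they do not

* `simulate_tree()` draws a pure-birth topology rescaled to a given
  ultrametric height. `evolve_proteins()` applies the same 20-state
  equal-rates model the distance correction assumes, with expected
  mismatch p = (19/20)(1 − exp(−(20/19)d)); no indels, so the true column
  map is the identity and alignment accuracy is scoreable.
  `simulate_two_families()` duplicates one species tree into two paralog
  subfamilies joined above their roots — the gene-duplication-precedes-
  speciation structure behind the reaction-specific clustering claim.
  Defaults (6 species, subtree height 0.15 substitutions/site, tip-to-tip
  inter-family divergence 0.9, lengths 330 and 260 for the two subunits)
  mirror a strongly two-clustered protein family of EtfA/EtfB size.
* `plant_genome()` lays out one etfA/etfB pair per requested context with
  its markers adjacent, among random decoy genes, back-translated with
  random codons, and emits GenBank and GFF3+FASTA from one internal model
  (so cross-format parser tests are meaningful) plus a machine-readable
  truth table. Planted genes sit at 70% identity to fixed synthetic
  reference proteins by default; decoys are unrelated random sequences
  (background identity ≈ 5%). Inter-cluster gaps default to six decoys so
  neighbourhoods do not overlap at the default window, as in real genomes
  where the clusters lie in separate regions.
* `simulate_fermentation()` applies a flux vector's exchange footprint to
  a starting medium (sodium lactate 7.41 g/L, sodium acetate 7 g/L, plus
  yeast-extract butyrate 4.6 mM and propionate 1 mM) and perturbs all
  measurements with multiplicative lognormal noise (default CV 5%, a
  typical HPLC/GC spread).

None of the generators model indel evolution, codon usage, rate
heterogeneity, horizontal transfer, sequencing or annotation error, or
time-course dynamics. Passing tests therefore demonstrate correctness of
the algorithms under the stated models, not robustness to every artefact
of real survey data; on real genomes the permissive homology thresholds
and the `ambiguous`/`unassigned` labels are the safety valves.

## Numerical choices and problem sizes

Alignment scores are real-valued doubles (the 0.1 gap extension is kept
exact); DP tie-breaks and UPGMA tie-breaks are fixed as described, so all
outputs are reproducible bit-for-bit given a seed. Distance saturation
caps at 10 substitutions/site. Flux feasibility uses a relative exchange
residual of 1e−6 and a closure tolerance of 1e−6 scaled by the largest
rate.

The shipped test-suite and acceptance runs use deliberately moderate
sizes — planted replicons of 15–35 genes, families of 12 tips × 260–330
residues, 100–200 bootstrap replicates, 50-seed clustering ensembles and
200-seed fermentation recovery ensembles — chosen so the full suite
completes in minutes on one core while the Monte-Carlo margins (support
≥ 95 in ≥ 90% of runs; 3σ recovery in ≥ 95%) remain comfortably
discriminating.
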