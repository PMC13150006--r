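---
title: "Methods: selectivity hotspots, interaction networks, and fold selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity hotspots, interaction networks, and fold selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexp)
```

`selexp` asks a comparative question about two receptor subfamilies: which
alignment positions are *conserved within* each subfamily yet *divergent
between* them, and are therefore candidate determinants of ligand
selectivity? This vignette documents the models and procedures, the defaults
and why they were chosen, what the synthetic-data generators do and do not
emulate, and the numerical decisions a maintainer should know about.

## The hotspot statistic

For each annotated alignment column the package computes, per subfamily, the
consensus residue (most frequent non-gap residue) and its conservation
(consensus count divided by the number of sequences). A shared position is a
hotspot when

- conservation ≥ θ in **both** subfamilies (θ defaults to 0.80), and
- `BLOSUM62(consensus_A, consensus_B) < 0`,

i.e. the position is under strong within-group constraint but the two groups
settled on chemically dissimilar residues. The statistic is symmetric in the
two groups because BLOSUM62 is symmetric.

Decisions taken where the convention was genuinely open:

- **Threshold inclusivity.** Descriptions of this rule alternate between
  "≥ 80 %" and "> 80 %". The package defaults to inclusive (≥ 0.80), with
  `hotspot_config(inclusive = FALSE)` for the strict reading. Positions of
  interest in practice are near-fully conserved, so the choice rarely
  matters; the synthetic generator enforces conservation exactly by count so
  tests can probe the boundary sharply.
- **Conservation denominator.** Gapped sequences count in the denominator by
  default — a gap is evidence against conservation at that position.
  `compute_consensus(..., denominator = "nongap")` switches to the non-gap
  convention.
- **Ties.** An exact frequency tie between residues is broken
  alphabetically. This is arbitrary but deterministic and documented; ties
  essentially never occur at conservation levels that pass θ.
- **BLOSUM62 as constants.** The 20×20 NCBI matrix is embedded in the
  package so scoring has no runtime data dependency; a test asserts identity
  with the copy shipped by Biostrings.
- **Column indexing.** Alignment columns are 1-based everywhere, following R
  convention. Annotation tables use 1-based *reference residue positions*
  (counting non-gap characters of the reference row), which makes the
  numbering invariant to gap-column insertion — a property test exercises
  this with random gap insertions.
- **Ambiguity codes.** B, Z, X, U, O, J are rejected by default (curated
  subfamily sets should not contain them); `ambiguous_to_gap = TRUE` maps
  them to gaps instead.

The combinatorial helper `chance_one_in(n, k)` computes the exact binomial
coefficient by interleaved multiplication and division — every intermediate
value is itself a binomial coefficient, so the computation is exact in
double precision below 2^53. `chance_one_in(100, 7)` = 16,007,560,800, the
reciprocal probability of hitting one specific 7-position set among 100
candidates by uniform chance ("one in ~16 billion").

## Structure annotation

**Binding sites.** A receptor residue is a binding-site residue when any of
its heavy atoms lies within the cutoff (default 4.0 Å, the conventional
agonist-contact definition) of any ligand heavy atom. The packaged
13-position ligand-contact list (`binding_site_positions()`) uses `45x54`
to denote the extracellular-loop-2 position two residues after `45x52`.

**Regions.** `default_region_table()` maps generic numbers to the three
hotspot regions: the orthosteric site, the TM2–TM7 interface
(2x60, 2x64, 7x35, 7x39, 1x46, 7x43) and the TM3–TM4–TM5 interface
(3x41, 3x42, 4x53, 5x46). Segment boundaries are approximate and the table
is user-overridable.

**Superposition.** `superpose_ca()` solves the least-squares rigid-body
problem with the Kabsch SVD construction; a reflection-only optimum is
corrected to a proper rotation (determinant +1). Pairing is by residue
number or by generic number; unmatched residues are dropped and counted.
Tests cross-check RMSD values against an independent least-squares fit
(bio3d) and verify invariance under random rigid transforms. Note that a
published whole-receptor Cα RMSD is only reproducible when the residue
subset behind it is known; the function reports `n_atoms_matched` so that
subset choices are explicit.

**Prioritisation.** The published deprioritisation of hotspots was a manual
structural judgement ("surface-exposed", "close to the G protein binding
site"). The package replaces it with explicit, overridable proxies: a
Shrake–Rupley-style sampled solvent accessibility (deterministic
golden-spiral lattice, 192 points/atom, probe 1.4 Å, Tien-style theoretical
maxima for relative exposure; threshold 0.4) and a Cα proximity test
(default 8 Å) against a user-marked intracellular reference set. An explicit
deprioritisation list always wins. Requesting the structural heuristics
without a structure is an error rather than a silent no-op.

## Trajectory networks

Residues are nodes; an edge requires a heavy-atom contact within 4.5 Å in at
least 75 % of frames. Sequence-adjacent residues (|Δresno| ≤ 1 on a chain)
are excluded — backbone neighbours are trivially in contact. Both cutoffs
and the adjacency window are arguments.

**Edge weights.** The convention adopted is `w_ij = -log|C_ij|`, where
`C_ij` is the normalised equal-time cross-correlation of Cα displacement
vectors: strongly correlated residues communicate at low cost. The mapping
from correlation to weight is not uniquely standardised across tools, so the
formula is documented here and the clamp (`w_max = 20` when
`|C| < e^{-20}`) is configurable. Frames are superposed onto the first frame
(Cα Kabsch fit) before computing displacements; without this, global
tumbling masquerades as correlated motion. Correlation on fewer than two
frames is a named degenerate-statistics error; a residue with zero variance
contributes zero correlation.

**Communities and paths.** Community detection is Girvan–Newman — iterative
removal of the highest-betweenness edge, taking the partition of maximum
modularity — delegated to igraph's edge-betweenness clustering with the
weights treated as distances. Shortest communication paths use a
Floyd–Warshall implementation with path reconstruction; tests compare its
distances against an independent single-source (Dijkstra) oracle on 100
random graphs, and brute-force modularity enumeration confirms the clique
benchmark.

**Geometric observables.** A hydrogen bond in a frame requires donor–
acceptor distance < 3.5 Å **and** donor–hydrogen–acceptor angle ≥ 120°
(inclusive); hydrogens are assigned to donors by a ≤ 1.2 Å D–H distance in
the first frame, and a donor without a hydrogen is a named error. χ1 is the
N–Cα–Cβ–Cγ torsion (Cγ analogue: CG1 for Val/Ile, OG1 for Thr, OG for Ser,
SG for Cys) with the IUPAC sign convention and range (−180°, 180°]; the
trans rotamer reports +180°, and tests pin the sign against an independent
torsion implementation. Occupancy comparisons use Welch's unequal-variance
t-test (two-tailed, Welch–Satterthwaite degrees of freedom); when both
samples are constant the test is degenerate and p = 1 (equal means) or 0 is
returned by convention.

## Pharmacology

The concentration–response model is the 3-parameter logistic with Hill slope
fixed at 1:

$$y(c) = \mathrm{basal} + \frac{\mathrm{emax} - \mathrm{basal}}
        {1 + 10^{-(\log_{10} c + \mathrm{pEC}_{50})}}$$

Fitting is bounded Levenberg–Marquardt least squares (pEC50 constrained to
[0, 14]) with multi-start initialisation: a data-driven guess (the
concentration nearest half-maximal response) plus a pEC50 grid 4–10; the
best deviance wins. A variable-slope 4-parameter fit exists behind
`variable_slope = TRUE` but is not the default. Responses are assumed
pre-normalised (percent of wild-type maximum); the package never normalises
silently. At least 4 points spanning ≥ 2 log units are required; a flat
response is reported as non-converged with a reason rather than producing a
meaningless pEC50.

Fold selectivity is `10^{ΔpEC50}`, reported at full precision and rounded to
two significant figures, the conventional reporting precision for such
ratios (2500-, 63-, 3400-fold and so on). One documented quirk of that
convention: recomputing a ratio from *already-rounded* two-decimal pEC50s
can land one reporting unit away from a value derived from unrounded fits —
e.g. printed potencies of 8.48 and 7.22 give 10^1.26 ≈ 18, where the
original unrounded fit evidently rounded to 19. The package always reports
what the inputs imply.

## Synthetic data: what it does and does not emulate

The generators produce data with exactly the statistical structure each
analysis assumes, so that every downstream test is a parameter-recovery
test with known truth:

- `simulate_alignments()` — two gapless alignments (defaults: 515 and 401
  sequences, the sizes of a realistic two-subfamily comparison, over 100
  candidate positions) sharing identical background columns, with planted
  divergent pairs (defaults: the five prioritized hotspot pairs V/S, F/S,
  N/V, K/G, E/L at 3x36, 45x52, 7x38, 2x60, 3x41) at exact-by-count
  conservation. Not emulated: phylogenetic correlation between sequences,
  gaps, alignment error, and compositional bias — so perfect planted-signal
  recovery demonstrates correctness of the caller, not expected performance
  on real subfamily alignments, where conservation estimates carry
  phylogenetic redundancy.
- `simulate_trajectory()` — single-Cα residues spaced 20 Å apart with
  isotropic Gaussian fluctuation (0.3 Å), planted contacts at 3.5 Å in a
  seeded random subset of frames, and correlated blocks sharing a common
  displacement mode scaled as $s = \sigma\sqrt{\rho/(1-\rho)}$ to hit a
  target correlation. Not emulated: bonded geometry, side chains, solvent,
  or any physical force field.
- `simulate_curves()` — logistic truth plus Gaussian noise on a log-spaced
  grid (defaults: 8 points over 7 log units, triplicates, noise 5 % of the
  maximal response, basal 0 and emax 100 as percent-normalised cAMP data).

All generators are integer-seeded and byte-reproducible.

## Problem sizes and tolerances in the test suite

The suite verifies: exact reproduction of eleven published fold values from
their pEC50 pairs; the exact binomial count C(100, 7); perfect planted-
hotspot recovery with brute-force oracle agreement on 100 random toy
alignments (≤ 10 sequences × ≤ 20 columns); planted contact occupancy within
±0.05 at 1000 frames; Girvan–Newman recovery of planted cliques;
Floyd–Warshall agreement with Dijkstra on 100 random 8-node graphs;
constructed hydrogen-bond and χ1 geometries to 10⁻⁶ degrees; noiseless
logistic recovery to 10⁻⁴ pEC50 units and a median absolute error < 0.1 at
5 % noise over 1000 simulated triplicate experiments. These sizes were
chosen to make sampling error negligible relative to each tolerance.

## Known limitations

- Hotspot conservation uses raw sequence counts; there is no phylogenetic
  down-weighting of redundant species, so over-sampled clades inflate
  conservation.
- The eligibility whitelist and region table approximate transmembrane
  boundaries; users comparing against a specific numbering scheme should
  supply their own tables.
- The contact-network correlation is Cα-based; side-chain-mediated coupling
  with a static backbone is invisible to it.
- Trajectory input is multi-model PDB or a plain per-frame table; binary MD
  formats need prior conversion.
- The exposure and G-protein-proximity prioritisation heuristics are
  proxies for a structural judgement call and should be reviewed, not
  trusted blindly.
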