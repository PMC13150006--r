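# selexp

Selectivity-hotspot discovery and ligand pharmacology for G-protein-coupled
receptor (GPCR) subfamilies.

Closely related receptors — the β-adrenergic and D1-like dopaminergic
subfamilies are the motivating case — bind near-identical catecholamine
ligands (adrenaline, noradrenaline, dopamine) with sharply different
potencies. `selexp` implements the comparative-sequence statistic used to
locate the residues responsible, together with the structural, dynamical and
pharmacological analyses that surround it:

- **Hotspot calling.** Given one multiple sequence alignment per subfamily
  and a generic-residue-number annotation (Ballesteros–Weinstein/GPCRdb
  style, e.g. `3x36`), a position is a *selectivity hotspot* when it is
  conserved within each subfamily (conservation ≥ θ, default 0.80) while the
  two subfamilies' consensus residues are chemically dissimilar under
  BLOSUM62, i.e. `BLOSUM62(cons_A, cons_B) < 0`.
- **Structure annotation.** Binding sites from ligand proximity (heavy atoms
  within 4 Å), region classification (orthosteric / TM2–TM7 / TM3–TM4–TM5),
  Kabsch Cα superposition with RMSD, and prioritisation heuristics
  (solvent exposure, proximity to the G-protein interface).
- **Trajectory networks.** Residue-interaction networks from coordinate
  ensembles: edges for heavy-atom contacts within 4.5 Å in ≥ 75 % of frames,
  weighted by `-log|C_ij|` where `C_ij` is the Cα displacement
  cross-correlation; Girvan–Newman communities; Floyd–Warshall shortest
  communication paths; hydrogen-bond occupancies (donor–acceptor < 3.5 Å,
  D–H–A angle ≥ 120°); χ1 rotamer series; Welch's t-tests on occupancies.
- **Pharmacology.** Three-parameter logistic fits of concentration–response
  data (`y = basal + (emax − basal) / (1 + 10^{-(log10 c + pEC50)})`, Hill
  slope 1) and fold selectivity `10^{ΔpEC50}`, reported at two significant
  figures.
- **Synthetic data.** Seed-controlled generators for subfamily alignments
  with planted hotspots, coordinate ensembles with planted contacts and
  correlated motions, and noisy logistic curves — every analysis is testable
  offline.

## Worked example

Simulate a pair of subfamily alignments (515 and 401 sequences over 100
annotated positions, with five planted divergent pairs) and call hotspots:

```r
library(selexp)

sim <- simulate_alignments(seed = 42)
calls <- call_hotspots(compute_consensus(sim$alignment_a, sim$map),
                       compute_consensus(sim$alignment_b, sim$map))
calls <- classify_regions(calls)
calls[calls$is_hotspot, ]
#>     generic_number consensus_a conservation_a consensus_b conservation_b
#> 29            2x60           G              1           K              1
#> 33            3x36           V              1           S              1
#> 36            3x41           E              1           L              1
#> 90            7x38           N              1           V              1
#> 100          45x52           F              1           S              1
#>     blosum62 is_hotspot      region priority
#> 29        -2       TRUE     TM2-TM7    unset
#> 33        -2       TRUE orthosteric    unset
#> 36        -3       TRUE TM3-TM4-TM5    unset
#> 90        -3       TRUE orthosteric    unset
#> 100       -2       TRUE orthosteric    unset
```

Each row is one annotated position: the two subfamily consensus residues
with their conservation fractions, the BLOSUM62 score of the consensus pair,
and the structural region. All five planted divergent pairs (V/S, F/S, N/V,
K/G, E/L) are recovered; the identical background positions are not called.

Fold selectivity from two potencies — adrenaline (pEC50 8.69) versus
dopamine (pEC50 5.29) at one receptor:

```r
fs <- fold_selectivity(8.69, 5.29)
sprintf("fold = %.1f -> reported %g", fs$fold, fs$fold_2sf)
#> "fold = 2511.9 -> reported 2500"
```

And the combinatorial argument for why a specific 7-position set out of 100
candidate positions is unlikely to be found by chance:

```r
format_one_in(chance_one_in(100, 7))
#> "one in ~16 billion"
```

A command-line interface wraps the same functions
(`inst/exec/selexp hotspots|annotate|network|pharm|fold|simulate`); see
`?selexp_main`.

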