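# mifscan

Comparative **molecular interaction field** (MIF) analysis for protein
families, in R.

Protein families with a conserved fold can still diverge sharply in what
their *surfaces* do: the electrostatic potential and hydrophobic character
around a protein decide which effectors, regulators and membranes it can
engage. `mifscan` is for structural bioinformaticians who have a set of
aligned structures (typically homology models on a shared template) and
want to know (i) which family members are interchangeable in
interaction-field terms, and (ii) *where* on the structure the fields are
conserved or divergent.

## What it computes

1. **Electrostatic potentials** — finite-difference solution of the
   linearized Poisson–Boltzmann equation
   `∇·(ε∇Φ) − ε_s κ² λ Φ = −4πCρ` (ε = 4 inside / 78 outside, 50 mM salt,
   1.4 Å surface probe, Debye–Hückel boundary conditions, red–black SOR),
   in kT/e on a regular grid (production default 110³ at 1 Å).
2. **Hydrophobic interaction fields** — a DRY-probe-style energy
   `E = Σ E_LJ + W_ENT − Σ E_HB` per grid node (0.5 Å default spacing),
   with all positive values clamped to 0, so polar regions carry no
   hydrophobic signal.
3. **Field comparison** — the Hodgkin similarity index
   `SI = 2Σab / (Σa² + Σb²)` over a *skin* of grid points 2–5 Å outside
   the molecular surface (−1 anticorrelated … +1 identical), and the
   distance `d = √(2 − 2·SI)` ∈ [0, 2]; globally and in 15 Å spheres
   around each residue's Cα (a per-residue conservation profile).
4. **Clustering** — UPGMA "epograms" (dendrograms in interaction-field
   space, Newick), ordered distance heatmaps (TSV/PNG) and per-residue
   conservation colour maps.
5. **Synthetic cohorts** — generated pseudo-protein families with known
   group structure for validation, plus an end-to-end `run_pipeline()`
   driver with manifest, logging and idempotent reruns.

PQR (APBS dialect) is the canonical input; PDB input gets a bundled
minimal charge/radius ruleset; fields are exchanged as OpenDX.

## Worked example

```r
library(mifscan)
coh <- make_cohort(cohort_spec())           # 12 proteins, 3 groups, seed 42
g   <- default_grid(coh$structures)         # shared 1-A grid, 10-A margin
ep  <- lapply(coh$structures, solve_lpbe, grid = g)
m   <- pairwise_global(ep, coh$structures)  # Hodgkin SI on pairwise skins
m$si[1:4, c(1, 5, 9)]
#>           g1_m1       g2_m1      g3_m1
#> g1_m1 1.0000000 -0.06996526 0.06214241
#> g1_m2 0.9993449 -0.07693287 0.06976699
#> g1_m3 0.9988522 -0.07483835 0.07352192
#> g1_m4 0.9987941 -0.06352630 0.06974123
```

Members of group 1 have essentially identical potentials (SI > 0.998,
distance ≈ 0.04) while cross-group pairs are uncorrelated (SI ≈ ±0.07,
distance ≈ √2): same backbone, different charge pattern. Clustering
recovers the generating groups exactly:

```r
epo <- build_epogram(m)                     # UPGMA on d = sqrt(2 - 2 SI)
epo
#> epogram: 12 leaves, upgma linkage, root height 0.7511
labs <- vapply(coh$structures, `[[`, character(1), "label")
table(cluster = cut_epogram(epo, 3)[labs], group = coh$labels)
#>        group
#> cluster 1 2 3
#>       1 4 0 0
#>       2 0 4 0
#>       3 0 0 4
```

The per-residue scan localises conservation (here moderate everywhere,
since the cohort diverges across its whole surface):

```r
prof <- conservation_profile(residue_scan(ep, coh$structures))
prof
#> conservation_profile (electrostatic): 24 residues, 0 flagged, mean SI 0.146
```

`write_epogram()`, `mif_heatmap()`, `write_profile_tsv()` and
`color_profile()` export Newick trees, ordered TSV matrices and colour
tables; `run_pipeline()` does all of the above from one config and writes
a JSON manifest. A thin command-line wrapper lives at
`inst/cli/mifscan.R`.

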