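---
title: "Comparing molecular interaction fields across a protein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing molecular interaction fields across a protein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifscan)
```

## The problem

Closely related proteins — isoforms of a GTPase family, paralogous enzymes,
homology models built on one template — often have nearly identical folds
but different *interaction properties*: the electrostatic potential and the
hydrophobic character of their surfaces. Those properties, not the backbone,
decide which effectors and regulators a family member can bind. `mifscan`
quantifies them as molecular interaction fields (MIFs) on a regular 3-D
grid, compares the fields pairwise across the family, clusters the proteins
in "interaction-field space", and scans each residue's neighbourhood to map
where in the structure the fields are conserved or divergent.

## Electrostatic potentials

The electrostatic MIF is the solution of the linearized Poisson–Boltzmann
equation (LPBE)

$$\nabla\cdot\big(\varepsilon(\mathbf r)\,\nabla\Phi(\mathbf r)\big)
 - \varepsilon_s\,\kappa^2\,\lambda(\mathbf r)\,\Phi(\mathbf r)
 = -4\pi C \rho(\mathbf r),$$

solved by finite differences on a uniform grid. Defaults follow common
practice for comparative surface-potential work: protein dielectric
$\varepsilon_p = 4$, solvent $\varepsilon_s = 78$, 50 mM monovalent salt
($1/\kappa \approx 13.6$ Å at 298.15 K), molecular surface from a 1.4 Å
water probe, 2 Å Stern (ion-exclusion) layer, and for production-scale
proteins a $110^3$ grid at 1 Å spacing. Potentials are reported in kT/e.

Numerical choices, each the standard one where several are defensible:

* **Molecular surface.** A grid-native two-pass morphological
  approximation of the solvent-excluded surface: nodes within
  `radius + probe` of an atom are candidate interior; candidates that a
  probe sphere centred on free solvent can still reach are re-opened.
  This differs from an analytic SES at the sub-grid-spacing level and is
  one reason absolute potentials differ slightly between solvers.
* **Charge spreading.** Trilinear assignment of each point charge to its
  8 surrounding nodes.
* **Boundary conditions.** Dirichlet faces from the sum of single-sphere
  Debye–Hückel potentials, one per charge. The solver never updates
  boundary nodes, so face values equal the analytic expression exactly.
* **Solver.** Red–black successive over-relaxation on the 7-point stencil
  with harmonic-mean face dielectrics; relative L2 residual tolerance
  `1e-5`, cap 10 000 iterations, relaxation factor
  $2/(1+\sin(\pi/n))$ by default. Divergence (a growing residual over
  five successive checks) raises an error carrying the residual trace.
* **Degenerate inputs.** A charge-free structure returns the identically
  zero field; atoms outside the grid, or charged atoms in the outermost
  two node layers, are geometry errors rather than silent truncation.

Because the LPBE is linear in its sources, negating all charges negates the
potential exactly, scaling charges scales it, and two charge sets
superpose; the test suite uses these identities (and the Coulomb and
Debye–Hückel closed forms in a uniform dielectric) as independent oracles.
On the point-charge test the solution at 10–20 Å matches the closed form to
better than 1% at 1 Å spacing, comfortably inside the 5% oracle band, and
halving the spacing roughly halves that error.

## Hydrophobic interaction fields

The hydrophobic MIF emulates a GRID-style DRY probe: at each node

$$E = \sum_i E_{\mathrm{LJ}}(d_i) + W_{\mathrm{ENT}} - \sum_j E_{\mathrm{HB}}(d_j),$$

followed by the clamp: **any positive value is reset to zero**, and nodes
inside atom cores are zero, so polar regions carry no hydrophobic signal
and the field is everywhere $\le 0$. The original DRY parameterisation is
proprietary, so the functional forms here are a documented surrogate and
absolute energies are not claimed — only the spatial pattern that the
similarity analysis consumes:

* apolar atoms (C, S; synthetic class `APO`) attract the probe through a
  shift-truncated 12-6 Lennard-Jones term
  ($\epsilon = 0.15$ kcal/mol, $r_{min} = 3.6$ Å, cutoff 8 Å) and define
  the first solvation shell (gap $\le 1.5$ Å) inside which the constant
  water-entropy reward $W_{\mathrm{ENT}} = -0.85$ kcal/mol applies;
* polar atoms (N, O; synthetic class `POL` side chains) contribute only
  the hydrogen-bond competition penalty, decaying linearly from
  2.5 kcal/mol at contact to zero at 4 Å. Their LJ well depth defaults to
  0 so that a structure made entirely of donors/acceptors yields the
  identically zero clamped field — the qualitative behaviour the clamp
  rule encodes.

The default hydrophobic grid spacing is 0.5 Å (the field is short-range
and needs the finer sampling); for comparisons the field is computed on a
refined grid nested in the electrostatics grid and downsampled node-for-node
back to 1 Å, so both field kinds share one skin mask.

## Comparing fields: skins, Hodgkin index, distances

Fields are compared only where binding partners feel them: a **skin** of
grid points whose gap to the nearest atom surface lies between 2 Å (the
skin probe) and 2 + 3 Å. For a pair of proteins the skins are intersected
by default (union and fixed-reference policies are available); with a
shared template backbone the skins nearly coincide and the policy is
immaterial, but intersection is robust when synthetic cohorts jitter the
geometry.

Over the masked points the **Hodgkin similarity index**

$$\mathrm{SI}_{ab} = \frac{2\sum a b}{\sum a^2 + \sum b^2}$$

ranges from $-1$ (anticorrelated) through 0 to $+1$ (identical in shape
and magnitude), and the associated distance

$$d = \sqrt{2 - 2\,\mathrm{SI}}$$

runs from 0 (identical) to 2 (anticorrelated). If both fields vanish on a
mask the index is *undefined* — deliberately distinct from 0
("uncorrelated") — and the matrix entry is flagged rather than imputed. A
mask below `min_points` (default 50) grid points is likewise flagged: too
few samples to call anything.

The per-residue scan repeats the comparison inside spheres of 15 Å radius
around each residue's C-alpha (consensus position across the cohort, since
members share residue indexing). The **conservation profile** averages the
defined pairwise SIs per residue; a residue where *no* pair has a defined
index — for hydrophobic fields, a region so polar that every field was
clamped to zero — is flagged and scored 0, which the colour maps render
black. Undefined entries never enter averages as zeros inside similarity
matrices; the score-0 convention applies only at the profile stage.

## Clustering and visualisation

The similarity matrix becomes an **epogram** — a dendrogram in
interaction-field space, by analogy with a phylogram — via UPGMA (average
linkage) on $d$; single and complete linkage are available, but UPGMA is
the convention in the field-comparison literature. Labels are sorted
before linkage, which fixes tie-breaking and makes the tree invariant to
input order. Heights follow the ultrametric convention (a pair merging at
distance $d$ sits under a node of height $d/2$), trees serialise to
Newick, and the ordered heatmap writes the permuted distance matrix as TSV
with an optional red (identical) to blue (dissimilar) PNG. Conservation
profiles map linearly onto a blue–green–red gradient over $[-1, 1]$ for
electrostatic scores and $[0, 1]$ for hydrophobic scores.

## The synthetic cohort: what it emulates, and what not

Real studies of this kind compare dozens of homology models built on one
or two template structures. Those models cannot ship with a package, so
`make_cohort()` generates the features that matter to the *pipeline*:
a shared, idealised backbone (an α-helical C-alpha trace, 1.5 Å rise,
100°/residue, one side-chain pseudo-atom per residue at 1.9 Å radius);
group structure (archetype charge patterns differing by a controlled
number of sign flips); within-group variation (per-site flip probability
and coordinate jitter); and alternating apolar/polar residue classes so
hydrophobic fields have structure.

Defaults — chosen once as a realistic desk-scale family and not tuned —
are 12 proteins in 3 groups over 24 residues with 8 charge sites:
archetypes differ by 4 sign flips (half the sites, a subfamily-scale
divergence), members flip each site with probability 0.05 and jitter
coordinates by 0.1 Å (isoform-scale noise), seed 42. On this cohort the
auto-sized grid is roughly $33 \times 33 \times 57$ at 1 Å and the full
pipeline (12 LPBE solves, all-pairs comparison, clustering, 24-residue
scan) runs in seconds; cutting the epogram at 3 clusters recovers the
true groups with adjusted Rand index 1.0.

What the synthetic cohort does *not* emulate: all-atom side chains and
their rotamers, sequence-dependent backbone variation, partial-charge
force fields (charges are unit formal charges), and membrane anchors or
other context. Passing tests therefore demonstrate that the machinery —
solver, masks, indices, scan, clustering — is correct and internally
consistent, not that any particular biological family will separate into
clean clusters.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `eps_interior` / `eps_exterior` | 4 / 78 | – | standard protein/water continuum values |
| `ionic_strength` | 0.050 | mol/L | physiological-scale screening, Debye length ≈ 13.6 Å |
| `surface_probe_radius` | 1.4 | Å | water-sized probe defining the molecular surface |
| `stern_layer` | 2.0 | Å | conventional ion-exclusion shell |
| grid spacing (EP / HIF) | 1.0 / 0.5 | Å | field range vs. cost; HIF is short-range |
| `skin_probe` / `skin_thickness` | 2 / 3 | Å | shell a partner atom can occupy |
| `sphere_radius` | 15 | Å | local neighbourhood of the residue scan |
| `min_points` | 50 | – | below this an SI is "no data", not 0 |

## Worked example

```{r example, eval = FALSE}
coh <- make_cohort(cohort_spec())          # 12 proteins, 3 groups, seed 42
g   <- default_grid(coh$structures)        # common 1-A grid, 10-A margin
ep  <- lapply(coh$structures, solve_lpbe, grid = g)
m   <- pairwise_global(ep, coh$structures) # Hodgkin SI over pairwise skins
epo <- build_epogram(m)                    # UPGMA on d = sqrt(2 - 2 SI)
table(cut_epogram(epo, 3), coh$labels)     # diagonal: perfect recovery
scan <- residue_scan(ep, coh$structures)   # 15-A spheres per residue
conservation_profile(scan)
```

Or end to end, with every artifact written to disk and a JSON manifest:

```{r pipeline, eval = FALSE}
run_pipeline(list(cohort = list(), fields = c("ep", "hif"),
                  outdir = "cohort_run", seed = 42))
```

## Known limitations

* Single-grid LPBE solves only — no coarse-to-fine focusing; very large
  boxes pay the full cost at the fine spacing.
* The SES approximation is grid-native; isocontours near the surface can
  differ from analytic-surface solvers by about a grid spacing.
* The DRY surrogate reproduces the qualitative apolar/polar field
  pattern, not GRID energies.
* Cohorts must share residue indexing (template-derived numbering);
  there is no built-in structural alignment or residue mapping.
* Hydrophobic conservation can formally produce negative SIs; profiles
  report them as computed, and the colour scale simply saturates at 0.
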