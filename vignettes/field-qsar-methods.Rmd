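---
title: "Field-based 3D-QSAR and end-state free energies: models, choices, limits"
author: "fieldqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR and end-state free energies: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldqsar)
```

# The modelling problem

Ligand-based 3D-QSAR assumes that, for a series of analogs binding the
same site in the same pose, differences in activity are explained by
differences in the steric, electrostatic and pharmacophoric environment
each molecule projects into the space around the shared scaffold. The
package quantifies that environment as probe interaction energies (CoMFA)
or Gaussian similarity indices (CoMSIA) on a rectangular lattice, and
regresses pIC50 on the resulting descriptor matrix with partial least
squares. A companion layer handles the arithmetic of end-state binding
free energies (MM-PB(GB)SA, LIE) computed elsewhere by an MD/solvation
engine: this package deliberately contains no docking, no dynamics, no
PB/GB solver — it consumes aligned structures and per-frame energy tables.

Everything downstream of file input is deterministic or explicitly
seeded, so a full analysis is reproducible bit-for-bit.

# Fields

## CoMFA

At every lattice point `q` the steric field is the Lennard-Jones energy of
an sp³-carbon probe (van der Waals radius 1.52 Å, +1 e charge):

$$E_S(q) = \sum_i \varepsilon_{ij}\left[\left(\tfrac{R_{min}}{r_{iq}}\right)^{12}
  - 2 \left(\tfrac{R_{min}}{r_{iq}}\right)^{6}\right],\qquad
  R_{min} = r^{vdW}_i + r^{vdW}_{probe},\;
  \varepsilon_{ij} = \sqrt{\varepsilon_i\,\varepsilon_{probe}}$$

and the electrostatic field is the Coulomb energy
$E_E(q) = 332.0636\sum_i q_{probe}\,q_i/(\varepsilon(r)\,r_{iq})$ in
kcal/mol. Both are clamped to ±30 kcal/mol *after* summation over atoms
(the conventional energy tolerance); a probe on top of an atom clamps to
+30 rather than propagating a singularity.

Choices that were genuinely open, and how they were fixed:

- **Dielectric.** A distance-dependent dielectric ε(r) = r is the default
  (the common choice when no explicit solvent model is present); plain
  ε = 1 is selectable via `dielectric = "constant"`.
- **Sterically excluded points.** Inside a molecule's van der Waals
  envelope, Coulomb values are physically meaningless. Where a molecule's
  steric field is clamped at +30, its electrostatic value is replaced by
  the column mean over the non-excluded molecules, and the replacement is
  flagged in the block's `imputed` slot. `exclusion = "clamp"` keeps the
  clamped values instead.
- **Atom parameters.** Element-keyed Bondi radii, Amber-like well depths,
  and sign-coded atomic hydrophobicity weights ship with the package
  (`atomParameterTable()`); they are deliberately simple (element-level,
  no valence typing) and overridable per call, because any specific
  commercial force field's parameters are both unavailable and
  unnecessary for the statistical machinery. Consequently *absolute*
  field values and field-contribution percentages will not numerically
  match those of a commercial engine on the same input; the PLS and
  validation layers are parameter-set agnostic.
- **Grid extent.** The lattice covers the union bounding box of the
  series expanded by a 4.0 Å margin at 2.0 Å spacing. Point ordering is
  x-fastest internally; OpenDX output converts to the z-fastest disk
  convention.

## CoMSIA

Similarity indices avoid the steep r⁻¹² wall:
$A_k(q) = -\sum_i w_{probe}\, w_{ik}\, e^{-\alpha r_{iq}^2}$ with no
distance cutoff and the literature-standard attenuation factor
α = 0.3 Å⁻². Property weights: steric ∝ r_vdW³, electrostatic = partial
charge, hydrophobic from the atom table, donor/acceptor 0/1 flags. With
non-negative weights the field is non-positive by construction.

## Column filtering

Columns with SD < 2.0 across the series are dropped before regression —
the standard minimum-sigma filter. The same numeric threshold is applied
to (unitless) CoMSIA columns; since CoMSIA values live on a smaller
scale, users mixing schemes should set `minSigma` per block rather than
rely on one value meaning the same thing in both.

# PLS, component selection, contours

The regression is NIPALS PLS1 on mean-centered X and y, *without*
autoscaling (grid fields share units within a scheme, and autoscaling
would inflate near-filtered columns). For a single response the NIPALS
weight vector per component has the closed form `w ∝ X'y`, so the fit is
exactly deterministic — no iterative refinement, no tolerance, no
starting-point sensitivity. Coefficient vectors are stored for every
cumulative component count; PLS solutions are nested, so one fit yields
predictions at any count.

- `SEE = sqrt(RSS/(n−c−1))` and `SEP = sqrt(PRESS/(n−c−1))` use the
  n−c−1 denominator (the convention behind the standard reporting
  tables); `F = (r²/c)/((1−r²)/(n−c−1))`.
- Leave-one-out cross-validation refits on every n−1 subset;
  `q² = 1 − PRESS/Σ(y−ȳ)²`. The ONC is the smallest component count whose
  q² lies within 0.005 of the profile maximum — a parsimony tie-break,
  since "optimal" alone would systematically pick noise-chasing extra
  components.
- Block scaling between field kinds is off by default; contributions per
  kind are reported as `Σ|coef|·SD` normalized to 100%.
- StDev*Coeff contour fields put `coef × SD` back on the lattice per
  kind, zero at filtered columns; display levels default to the 80th
  percentile of positive values (favored) and 20th of negative
  (disfavored).

# Validation battery

Internal fitness uses χ² = Σ(yᵢ−ŷᵢ)²/yᵢ² and RMSE with the n−1
denominator. The χ² denominator is typeset ambiguously in parts of the
QSAR literature (yᵢ vs yᵢ²); the package defaults to yᵢ² and exposes
`chiDenominator = "y"` — none of the package's own acceptance checks
depend on the choice.

External metrics on a held-out test set: through-origin slopes
`k = Σyŷ/Σŷ²`, `k′ = Σyŷ/Σy²`; `r₀²`/`r′₀²` from the corresponding
through-origin fits; `rm² = r²(1−√|r²−r₀²|)` and its primed/mean/delta
variants; `QF₃²`, which normalizes test error by *training* variance and
is therefore 1 for perfect prediction regardless of test-set composition;
and Lin's concordance correlation (biased 1/n moment convention), which
penalizes location/scale shifts that Pearson correlation ignores. Pass
flags follow the conventional thresholds (0.85 ≤ k, k′ ≤ 1.15;
|r₀²−r′₀²| < 0.3; (r²−r₀²)/r² < 0.1; rm² > 0.5; QF₃² > 0.6).

## Progressive scrambling

The stability question: how fast does cross-validated Q² degrade as the
response is progressively corrupted? The published descriptions of the
method fix the scramble count (100) and bin-size range (2–10) but not the
perturbation schedule, so the package documents its own: for each
scramble a bin size is drawn in [2, 10], sorted y is partitioned into
bins, and a perturbation of strength s ∈ [0, 1] (swept across scrambles)
is applied as `ceiling(s·n)` swaps, each within a random bin with
probability 1−s or between arbitrary positions with probability s. Mild
strengths therefore shuffle within activity bins (high r²_yy′), strong
strengths approach a full permutation. Q² and cSDEP = √(PRESS/(n−c−1))
are regressed quadratically on r²_yy′ and read off at the critical
perturbation r²_yy′ = 0.85, where the derivative of the Q² quadratic is
the sensitivity slope dq²/dr²_yy′; a slope ≤ 1.2 classifies the model as
stable. The zero-strength scramble is the exact identity, so the Q²
profile anchors at the unperturbed cross-validation — a property the test
suite checks to 1e−9. Whether cSDEP should be evaluated at the same
critical point as the slope is not specified anywhere authoritative; the
package evaluates both at 0.85 for coherence.

## Applicability domain

Leverages are hat values in the model's latent-score space,
`hᵢ = 1/n + tᵢ'(T'T)⁻¹tᵢ` on centered training scores (the 1/n term is
the intercept column, so the training centroid has leverage exactly 1/n);
test compounds are projected through `R = W(P'W)⁻¹`. The warning leverage
is h* = 3(p+1)/n with p = ONC. A compound is flagged when h > h* or its
standardized residual (residual / SD of training residuals) exceeds 3 in
magnitude. Note that published QSAR studies sometimes report h* values
inconsistent with this formula at their stated n and ONC (different
toolboxes compute leverage in different descriptor spaces); this package
states its space — latent scores — explicitly.

# End-state free energies

The aggregation layer implements the identities
ΔG_gas = ΔE_vdW + ΔE_ele, ΔG_solv = ΔG_PB/GB + ΔG_SA,
ΔTOTAL = ΔG_gas + ΔG_solv over component means taken across the final
trajectory window (default: last 200 frames, i.e. the final 2 ns at 10 ps
spacing). The entropy term −TΔS has *no field* in the breakdown class —
it is excluded by construction, matching the common practice of omitting
the computationally fraught normal-mode estimate. Reports round to 2
decimals for table parity but store full precision; published tables
assembled from independently rounded components can disagree with their
own totals by ±0.01, so comparisons against printed rows should tolerate
that drift.

LIE: ΔG_bind = α(⟨V_vdW⟩bound − ⟨V_vdW⟩unbound) + β(⟨V_ele⟩bound −
⟨V_ele⟩unbound), with the empirical neutral-ligand scaling α = 0.181,
β = 0.43 as defaults.

Per-residue decomposition tables are filtered by the 4.0 Å
minimum-distance rule and a negligibility threshold on |contribution|.
The threshold behind "negligible" is not standardized; the default is
0.05 kcal/mol and configurable. When no distance column is present only
the negligibility rule applies.

# The synthetic-data generator

`genMoleculeSeries()` builds 40 analogs (default) sharing a rigid planar
diamino-azine-like scaffold — a six-membered ring with two ring nitrogens
and two exocyclic amine nitrogens whose coordinates are bit-identical
across the series — decorated with 2–8 R-group atoms placed in a 1.5–4 Å
shell around the two attachment points, with randomized elements
(C/N/O/F/S), zero-sum partial charges and donor flags. This emulates a
common-substructure-aligned congeneric series.

`plantActivity()` makes pIC50 a linear function of post-filter field
columns plus N(0, 0.2²) noise, rescaled so the noise-free range equals
3 log units (matching a series whose IC50 spans ~13.9 nM to ~15111 nM
with a least-active baseline pIC50 of 4.8). Planting on *post-filter*
columns guarantees the signal survives column filtering — where a real
signal lives relative to the filter is unknowable in general, so the
generator makes the recoverable case explicit. By default the planted
weights follow the two dominant latent directions of the filtered field
matrix, each truncated to its 20 largest loadings (planted rank 2). This
choice is deliberate: activity in a congeneric series tracks dominant,
spatially coherent substituent variation (e.g. bulk at one R-position),
not an arbitrary sparse set of isolated lattice cells. A k-sparse signal
orthogonal to the dominant field variance is statistically adversarial
for PLS — cross-validated recovery stalls around q² ≈ 0.6 even
noise-free — whereas the low-rank planted default lands recovery in the
q² ≈ 0.8–0.9 regime with ONC ≤ 3, the behaviour real field-activity
datasets of this size exhibit. Both planting styles remain available via
`plantedCoefficients`.

What the generator does *not* emulate: real chemistry (bond topology,
conformational variability, correlated charge distributions), alignment
error, activity cliffs, or inter-assay noise structure. Passing the
recovery suite therefore demonstrates that the pipeline's statistics are
implemented correctly and recover known structure under realistic
dimensions and noise — it does not certify predictive performance on any
real chemical series.

`genEnergyFrames()` draws independent Gaussian frames about stated
component means — stationary by construction, with none of the
autocorrelation of a genuine MD trajectory; sufficient for testing
averaging and aggregation, not for testing convergence diagnostics (out
of scope).

# Numerical and scale choices

- Problem sizes throughout the test suite were chosen for fast, exact
  oracle comparisons: the standard series is 40 molecules on a ~1000-point
  lattice (~280 post-filter columns), LOO loops are exhaustive (no
  approximation), and the scrambling analysis defaults to 100 scrambles.
  A full analysis at these sizes completes in seconds.
- All RNG flows through explicit integer seeds (`withr::with_seed`);
  none of the package functions touch the global RNG state.
- Degenerate inputs error early with actionable messages: zero-variance
  response, over-large component counts, all-columns-filtered blocks,
  inverted bin ranges, empty ensembles, singular score cross-products.
- pIC50 is fixed as −log10(molar IC50) = 9 − log10(IC50 in nM).
- The train/test split stratifies by activity tertile only; structural
  diversity is not enforced (a documented limitation — diversity criteria
  are not algorithmically specifiable without a similarity threshold
  convention).

# Known limitations

- CoMFA/CoMSIA absolute values depend on the built-in atom parameter
  table; field-contribution percentages are comparable *within* analyses
  run with one table, not across parameter sets.
- MOL2 reading covers the Tripos ATOM/BOND records as parsed by bio3d;
  exotic records are ignored.
- The SDF writer emits a zero-bond connection table (fields depend only
  on atoms); round-trip preserves coordinates, charges, flags and core
  indices, not bond orders.
- No multi-response PLS, no kernel variants, no variable selection beyond
  the minimum-sigma filter, no bootstrap statistics.
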