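---
title: "Methods: skeletal dissolution, unit chains, and the reef keep-up model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeletal dissolution, unit chains, and the reef keep-up model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdiss)
```

`reefdiss` chains three pieces of science: a laboratory dissolution
experiment on coral skeletons, a unit-conversion chain from measured weight
loss to vertical reef-framework change, and an accretion–dissolution model
compared against sea-level projections. This vignette documents the models,
their assumptions, the parameter defaults, and the choices made where the
design was genuinely open.

## 1. The dissolution experiment and its analysis

Dead coral skeletons have no tissue or internal pH regulation, so at pH 7.8
they dissolve passively. The experimental design analyzed here exposes
skeletal fragments (≤ 5 cm) of a perforate genus (*Montipora*, four growth
forms) and an imperforate genus (*Pectinia*, foliose only) to pH 7.8
seawater for 7 days, with pH 8.2 controls, recording initial/final dry
weight (g), wax-dip surface area (cm²) and displacement volume (mL).

Three derived quantities drive the analysis:

- **Normalized loss** `(w₁ − w₀)/w₀` (dimensionless; negative while
  dissolving). Dividing by initial weight corrects for fragment size. The
  sign convention stores losses as negative numbers throughout the package,
  even where prose would quote a positive "loss".
- **Areal rate** `(w₁ − w₀)/(SA · days)` in g cm⁻² d⁻¹.
- **The exponential surface-area model** `loss = −k_amp · exp(k_exp · SA)`,
  with amplitude `k_amp` (g) and exponent `k_exp` (cm⁻²). The reference
  values for a 7-day perforate exposure are `k_amp = 0.005` g and
  `k_exp = 0.017` cm⁻²: internal pore space makes larger colonies expose
  disproportionately more reactive surface.

**Group comparison.** The headline test is a one-way ANOVA across five
groups of acidified samples — the four *Montipora* growth forms plus
*Pectinia* — with Tukey's HSD post-hoc, both computed on the classical
pooled-variance decomposition (`stats::lm`/`stats::aov` underneath).
Grouping is a parameter (`analysis_groups()` is just the default
labelling), since the growth-form versus porosity contrast can be read more
than one way. A degenerate layout with zero within-group variance is
reported with `degenerate = TRUE`, F = ∞ (or 0) and p = 0 (or 1) rather
than an error, because noiseless synthetic data hit it legitimately.

**Nonlinear fit.** `fit_exponential_loss()` is a two-parameter Gauss–Newton
iteration with step halving: start values come from regressing
`log(−loss)` on SA over the strictly negative losses (exact on noiseless
data), refinement uses all points, so weight-gaining samples stay in the
least-squares objective while being excluded from the logarithmic
initialization only. Convergence is declared at a relative parameter change
below 1e-10, capped at 200 iterations; non-convergence raises a condition
carrying the last iterate. Standard errors come from the Jacobian
cross-product at the optimum. Volume is validated and carried through but
enters no model: the experiment found no volume–dissolution relationship,
consistent with dissolution being a surface (not bulk) process.

## 2. The unit chain

`areal_mass_rate()` objects convert exactly between {g, kg} × {cm², m²} ×
{d, y} with a fixed 365-day year — a deliberate simplification; leap-day
accounting is far below the uncertainty of extrapolating week-scale
dissolution to decades. The conversion to vertical framework change is

> v [mm y⁻¹] = r [kg m⁻² y⁻¹] / (ρ [g cm⁻³] · (1 − φ)),

where ρ is the mineral density (default 2.9 g cm⁻³, aragonite — not a
measured value here but the standard crystal density) and φ the framework
porosity (default 0.5, the average-reef assumption). At these defaults a
perforate loss of 15.3 kg m⁻² y⁻¹ is −10.55 mm y⁻¹ of framework, and
production rates of 10, 4 and 1 kg m⁻² y⁻¹ correspond to roughly 7, 3 and
0.75 mm y⁻¹ of accretion — the three density classes used by the reef
model.

**A documented inconsistency.** The chain "0.000042 g cm⁻² d⁻¹ = 0.42
g m⁻² d⁻¹ = 15.3 kg m⁻² y⁻¹" that motivates the perforate dissolution input
is internally inconsistent by a factor of 100: 0.42 g m⁻² d⁻¹ × 365 =
0.153 kg m⁻² y⁻¹. `reefdiss` performs only exact conversions and therefore
does **not** reproduce 15.3 as a conversion of 0.42. Because the model
narrative (and its "3× the modern reef growth rate of 4 kg m⁻² y⁻¹"
comparison) is built on the 15.3 figure, the package takes 15.3 kg m⁻² y⁻¹
as the configured perforate-dissolution input (`units$perforate_loss_kg_m2_y`
in the pipeline config) and derives D = 10.55 mm y⁻¹ from it. Users who
prefer the strictly converted value can set the config field to 0.153.

## 3. Sea-level projections

Two generation modes cover the 1990–2100 horizon, both anchored at H = 0 in
1990 on an annual grid:

- **Semi-empirical**: `dH/dt = a_sl (T − T₀) + b_sl dT/dt`, integrated with
  the same fixed-step RK4 as the reef model from a scenario temperature ramp
  (linear by default; a zero-initial-slope monotone cubic is available).
  Defaults `a_sl = 5.6 mm y⁻¹ K⁻¹`, `b_sl = −49 mm K⁻¹`, `T₀ = −0.41 °C`
  follow the published dual-term semi-empirical calibration; they are
  exposed in `sealevel_params()` because different calibrations exist.
- **Parametric** (the scenario-matrix default):
  `H(t) = rise₂₁₀₀ · ((t − t₀)/(t₁ − t₀))^p` with `p = 2`, hitting the 2100
  endpoint exactly with an accelerating shape. Scenario endpoints default to
  B1 → 750 mm, A2 → 850 mm, A1FI → 900 mm, spanning the 75–90 cm range of
  recent projections (their average rate over a century, 9 mm y⁻¹, is about
  double the older 20–60 cm estimates' 4 mm y⁻¹). Exponents below 1 are
  rejected: decelerating sea-level rise is out of scope.

The exact plotted curves behind the published scenario figures are not
tabulated anywhere, so no figure-digitized values are asserted; the
parametric mode exists precisely so the endpoint and shape assumptions are
explicit and overridable. Scenario temperature targets are +1.8 °C (B1),
+3.4 °C (A2) and +4.0 °C (A1FI, also accepted under its "A1F1" spelling).

## 4. The reef accretion–dissolution model

The governing ODE is `dA/dt = (a·A)/A + b·S − (c·D)/A` with A the accreted
framework (mm), a the net accretion coefficient, b·S sedimentation
(1 mm y⁻¹ "for consistency") and c·D dissolution. The first term reduces
algebraically to `a`. The dissolution term's division by A is dimensionally
ambiguous (the original solver code is not available), so both readings are
implemented and labelled:

- **constant** (default): `dA/dt = a + b·S − c·D`. This is the only reading
  that reproduces the narrative magnitudes (e.g. a perforate high-cover reef
  at 7 + 1 − 10.55 ≈ −2.5 mm y⁻¹, giving −275 mm over 110 years).
- **literal**: `dA/dt = a + b·S − c·D/A`, dissolution damped by accumulated
  framework, with A floored at ε = 1 mm (configurable); reaching the floor
  sets a non-fatal `framework_exhausted` flag on the trajectory. A0
  defaults to 100 mm — an arbitrary antecedent-framework thickness, stated
  nowhere, and exposed as a parameter. No published number is claimed for
  this mode.

Integration is classical fixed-step 4th-order Runge–Kutta (step 0.1 y,
reported annually). The integrator is shared verbatim with the sea-level
module; it is exact for constant right-hand sides and its 4th-order
convergence on the literal-mode nonlinearity is verified by step-halving in
the test suite. RK4 was written in-package (15 lines) rather than through an
ODE-suite dependency so that the identical scheme, the floor flag and the
annual reporting grid are guaranteed across both modules.

**Keep-up diagnostics.** `keep_up_report()` rebases reef and sea trajectories
to their first common year and reports (i) the gap H − ΔA, (ii) the
*submergence year* — first year the gap exceeds a threshold (default 0 mm),
(iii) the *rate-crossover year* — first year the sea-level rise rate exceeds
the reef's accretion rate (centered finite differences on the annual grid).
Both are reported because "no longer keeping up" can reasonably mean either;
under the defaults an imperforate high-cover reef (net 8 mm y⁻¹) crosses
rates with the A1FI curve in 2044 (closed form: 1990 + 8·110²/(2·900) ≈
2043.8) but does not open a positive cumulative gap until the 2090s.
`scenario_matrix()` runs 3 densities × 2 porosity classes × 3 scenarios =
18 combinations; all perforate rows decline monotonically (best net rate
7 + 1 − 10.55 < 0).

## 5. The synthetic-data generator

No experimental table is deposited with the study, so `reefdiss` ships a
seeded generator emulating the design: 15 + 15 colonies, 7-day exposure,
acidified perforate losses drawn from the exponential model plus additive
Gaussian noise (sd 0.01 g), acidified imperforate and all control losses
Gaussian around exactly zero — encoding the finding that imperforate
treatment losses were indistinguishable from controls, with no surface-area
dependence.

Choices the design left open, fixed once here:

- **Surface areas** are uniform on [20, 250] cm² (not reported; chosen so
  the exponential term spans ~1.4× to ~70× its base, giving the curvature
  the fitted model implies). Within *Montipora*, the four growth forms
  occupy consecutive quarter-bands of that range (submassive < encrusting <
  branching < foliose), so the pooled draw stays uniform while foliose
  colonies expose the most surface and dissolve the most — the growth-form
  ordering the experiment reported. *Pectinia* spans the full range.
- **Initial weights** scale allometrically with surface area (areal skeletal
  density uniform on 0.15–0.25 g cm⁻², clipped to [5, 50] g): dry weight and
  wax-dip area of the same fragment are strongly correlated, and an
  independent weight draw would make normalized losses vary over orders of
  magnitude within groups, which the measured group structure rules out.
- **Treatment assignment** defaults to `"split"`: colonies alternate
  acidified/control within each genus × growth-form stratum (30 rows);
  `"paired-control"` doubles each colony into both arms (60 rows).
- **Noise** is additive Gaussian on the loss (sd 0.01 g for both arms) —
  the least-structured choice; the true balance and wax-dip measurement
  errors are unreported, so these are placeholders, not estimates.
- Final weights are clipped to stay positive; clipping more than 5 % of
  samples flags the design as too noisy.

What the generator does **not** emulate: carbonate-system chemistry of the
incubation water (alkalinity was not measured in the underlying experiment),
flow effects (advection can more than double dissolution rates), temporal
dynamics within the 7 days, and any real biological covariance between
growth form and skeletal density. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers what it assumes — parameter recovery,
group separation, power — not that the field values are correct.

Under the defaults (fixed seeds, measured by the test suite): the n = 50
recovery simulation returns `k_exp` within 10 % and `k_amp` within 25 % of
the generating values; the five-group ANOVA is significant in ≥ 90 % of 100
seeds; the imperforate exponent CI covers zero (or the fit is rejected for
lack of negative losses) in ≥ 90 % of seeds; and the mean perforate areal
rate lands within a factor of two of 4.2 × 10⁻⁵ g cm⁻² d⁻¹ — an
order-of-magnitude calibration, not an equality claim.

## 6. Numerical choices and limitations

- Year length 365 d; no leap handling.
- Time grids: annual reporting 1990–2100; internal integration step 0.1 y
  (convergence-tested; constant-mode results are step-independent).
- The simulation spans and replicate counts used in the tests (110-year
  horizons, 100-seed power loops, n = 50 recovery fits) were chosen as the
  smallest sizes at which the quantities of interest are stable.
- Gauss–Newton tie-breaks: step halving stops at λ < 1e-12 (the iterate is
  then kept); singular normal equations abort refinement and report the
  current iterate with non-convergence.
- `tukey_hsd()` treats group differences at rounding-noise scale
  (≤ 1e-8 relative) as exact ties when the pooled variance is zero.
- Regional sea-level processes (isostasy, tectonics, land use), spatial reef
  topography, hydrodynamic forcing and separate bioerosion are all out of
  scope; bioerosion is folded into the accretion coefficient a.
- The keep-up conclusion is sensitive to the parametric exponent p and the
  endpoint choice; both are config fields precisely because the underlying
  curves are not tabulated.
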