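# reefdiss

Coral-skeleton dissolution and reef accretion under ocean acidification.

When seawater pH falls to ~7.8 (the level projected for 2100), bare coral
skeletons dissolve passively. How fast they dissolve depends on skeletal
architecture: *perforate* corals (e.g. *Montipora*, *Acropora*, *Porites*)
have porous walls that expose large internal surface areas to seawater, while
*imperforate* corals (e.g. *Pectinia*, faviids) have fused, solid walls.
`reefdiss` is an analysis pipeline for dissolution experiments on such
skeletons and for the downstream question those experiments feed: can reefs
still accrete fast enough to keep up with sea-level rise?

The package is aimed at reef carbonate-budget researchers and provides:

- **Unit-checked flux conversions.** Areal CaCO₃ mass rates (g cm⁻² d⁻¹ ↔
  kg m⁻² y⁻¹, 1 y = 365 d) and their vertical-framework equivalents,
  `v [mm y⁻¹] = r [kg m⁻² y⁻¹] / (ρ (1 − φ))` for mineral density ρ
  (default 2.9 g cm⁻³, aragonite) and framework porosity φ (default 0.5).
- **Dissolution-experiment analysis.** Normalized weight loss
  `(w₁ − w₀)/w₀`, per-sample areal rates, group summaries, one-way ANOVA
  with Tukey HSD post-hoc, and a Gauss–Newton fit of the exponential
  surface-area model `loss = −k_amp · exp(k_exp · SA)`.
- **A family-level porosity reference table** for scleractinian corals
  (404 perforate and 432 imperforate species globally).
- **Sea-level projections 1990–2100** for the B1 (+1.8 °C), A2 (+3.4 °C) and
  A1FI (+4.0 °C) emission scenarios: a semi-empirical temperature-driven
  model `dH/dt = a·(T − T₀) + b·dT/dt` and a parametric power-law curve
  anchored at the 2100 rise.
- **An accretion–dissolution reef model**, `dA/dt = a + b·S − c·D`
  (optionally with the dissolution term damped by accumulated framework,
  `− c·D/A`), integrated with classical fixed-step RK4, plus keep-up
  diagnostics (rate-crossover year, submergence year) against any sea-level
  trajectory, over a 3 densities × 2 porosity classes × 3 scenarios matrix.
- **A seeded synthetic-data generator** reproducing the experimental design
  (15 perforate *Montipora* colonies across four growth forms + 15
  imperforate *Pectinia*, pH 7.8 treatment vs pH 8.2 control, 7-day
  exposure), so the whole pipeline is testable without any external data.

## Worked example

```r
library(reefdiss)
res <- run_pipeline()   # default config: synthetic experiment, seed 1

res$fit
#> Exponential dissolution model: loss = -k_amp * exp(k_exp * SA)
#>   k_amp = 0.00388136 g (se 0.000962)
#>   k_exp = 0.0180819 cm^-2 (se 0.00106)
#>   RSS = 0.0007215 on n = 8 (9 iterations)

cat(sprintf("five-group ANOVA: F = %.2f on (%d, %d), p = %.2g\n",
            res$anova$F, res$anova$df_between, res$anova$df_within,
            res$anova$p))
#> five-group ANOVA: F = 12.90 on (4, 11), p = 0.00039

res$manifest$perforate_vertical_rate_mm_y
#> [1] -10.55172

subset(res$matrix, porosity == "imperforate" & density == "high",
       select = c(scenario, net_rate, keeps_up, rate_crossover_year))
#>    scenario net_rate keeps_up rate_crossover_year
#> 13       B1        8     TRUE                2055
#> 14       A2        8     TRUE                2047
#> 15     A1FI        8    FALSE                2044
```

Reading the numbers: the nonlinear fit on the synthetic acidified perforate
subset recovers the generating curve (k_amp ≈ 0.005 g, k_exp ≈ 0.017 cm⁻²);
the five-group ANOVA (four *Montipora* growth forms + *Pectinia*, acidified
samples) is strongly significant because perforate colonies dissolve and
imperforate ones do not. A measured perforate loss of 15.3 kg CaCO₃ m⁻² y⁻¹
converts to −10.55 mm y⁻¹ of vertical framework loss at 50 % porosity, so
every perforate reef configuration has a negative net accretion rate and
declines monotonically. An imperforate reef with high coral cover (net
8 mm y⁻¹) keeps pace under the milder scenarios but loses the rate race to
the accelerating A1FI curve in the mid-2040s — the "keep-up until about
2050" result.

A command-line front end over the same functions is installed at
`system.file("cli", "reefdiss.R", package = "reefdiss")` with subcommands
`simulate-experiment`, `analyze-dissolution`, `project-sealevel`,
`run-reef-model`, `keep-up`, `scenario-matrix` and `all`.

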