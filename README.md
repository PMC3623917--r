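# roughscape

Time-scale-resolved analysis of how the hydration shell reshapes a
protein's potential-energy surface (PES).

Molecular-dynamics energy decompositions yield two time series on a
uniform grid: the protein self energy *E*<sub>p</sub> and the
protein–water interaction energy *E*<sub>p–w</sub> (kcal/mol). Their sum
*E*<sub>tot</sub> is the energy surface the solvated protein actually
moves on. On each time scale τ, `roughscape` cuts many windows of
*n* = 2<sup>m</sup> points spaced τ apart, and for every window computes
the population standard deviations σ<sub>p</sub>, σ<sub>p–w</sub>,
σ<sub>tot</sub> (the roughness of each surface on that scale) and the
Pearson correlation *r* between the two components, linked by the exact
sample identity

> σ²<sub>tot</sub> = σ²<sub>p</sub> + σ²<sub>p–w</sub> + 2 *r* σ<sub>p</sub> σ<sub>p–w</sub>.

Windows are classified on the (Δσ = σ<sub>tot</sub> − σ<sub>p</sub>, *r*)
plane: quadrant III (Δσ < 0, *r* < 0) means water *smooths* the
protein's landscape in that window, quadrants I and IV mean it
*roughens*, and quadrant II is algebraically impossible — the package
treats any occurrence as data corruption and fails loudly. Per scale it
reports mean *r*, mean σ's, their histograms, the roughening/smoothing
probabilities P(σ<sub>tot</sub> ≥ σ<sub>p</sub>) vs
P(σ<sub>tot</sub> < σ<sub>p</sub>), and quadrant occupancy — the
quantities that separate solvent *slaving* from *lubrication*
scale by scale.

The package is for structural-bioinformatics and molecular-modelling
researchers who already have component energy series (plain columnar
files, or NAMD-style logs with user-declared column sets) and want a
tested, deterministic, tidyverse-native pipeline from those series to
per-scale summaries and figures. A coupled multi-timescale
Ornstein–Uhlenbeck generator with closed-form oracles makes every stage
testable without MD data.

## Worked example

Two components — a fast, weakly coupled one and a slow, water-dominated,
anticorrelated one — reproduce the qualitative hydration signature:

```r
library(roughscape)
library(dplyr)

model <- synthetic_model(
  rbind(ou_component(theta = 2,    a = 1,   b = 1,   rho = 0),
        ou_component(theta = 2000, a = 0.5, b = 2.5, rho = -0.9)),
  n_steps = 2e5, seed = 42
)
model_moments(model)
#>   var_p var_pw   cov var_tot  r_inf
#> 1  1.25   7.25 -1.12    6.25 -0.374

series <- simulate_series(model)
report <- analyze_landscape(series, scales = c(1, 8, 64, 512),
                            m = c(5, 6), max_windows = 1000)
tidy(report) |> filter(m == 6) |>
  select(tau, mean_r, mean_sigma_p, mean_sigma_pw, mean_sigma_tot,
         p_rough, p_smooth)
#>     tau  mean_r mean_sigma_p mean_sigma_pw mean_sigma_tot p_rough p_smooth
#> 1     1 -0.0103        0.957         0.994           1.37   0.998    0.002
#> 2     8 -0.0650        0.996         1.21            1.51   1        0
#> 3    64 -0.229         1.04          1.89            1.93   1        0
#> 4   512 -0.367         1.10          2.61            2.43   1        0
```

Reading the table: at the finest scale the components are nearly
uncorrelated and the total surface is rougher than either
(σ<sub>tot</sub> ≈ √(σ²<sub>p</sub> + σ²<sub>p–w</sub>)); as τ grows the
slow anticorrelated component dominates, mean *r* falls towards the
full-process value −0.374, all roughnesses grow, and σ<sub>tot</sub>
drops below σ<sub>p–w</sub> while staying above σ<sub>p</sub> — water
roughens the landscape in essentially every window here (p_rough ≈ 1),
even though the energies anticorrelate.

`autoplot(report, "correlation")`, `"roughness"`, `"probabilities"` and
`"quadrants"` draw the standard figures; `write_report(report, dir)`
writes deterministic TSV/JSON tables; `compare_exponents(report)`
tabulates the m = 5 vs m = 6 discrepancy. `read_energy_series()` /
`read_analysis_config()` + `run_analysis()` drive the same pipeline from
files and a YAML config, and `inst/scripts/roughscape.R` wraps it for the
shell (`simulate`, `analyze`, `compare`).

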