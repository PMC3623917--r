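---
title: "Multi-scale roughness and correlation analysis of protein–water energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale roughness and correlation analysis of protein-water energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(roughscape)
library(dplyr)
```

## The question and the model

Whether the hydration shell *drives* protein conformational dynamics
(solvent slaving) or *facilitates* it (lubrication) can be framed as a
question about the protein's effective potential-energy surface (PES):
does the protein–water interaction energy make that surface rougher or
smoother, and on which time scales?

`roughscape` analyses two energy time series sampled on a uniform grid of
spacing $\delta$ — the protein self energy $E_p(t)$ and the protein–water
interaction energy $E_{p\text{–}w}(t)$, both in kcal/mol — together with
their sum $E_{tot} = E_p + E_{p\text{–}w}$, the energy that actually
governs the solvated protein's conformational motion. $E_{tot}$ is always
recomputed from the two components, never stored, so the variance
decomposition below is a *testable identity* of every analysis, not an
assumption.

On a time scale $\tau$, roughness is quantified by the population standard
deviation of $n$ consecutive energy values spaced $\tau$ apart,
$\sigma = \sqrt{\langle E^2\rangle - \langle E\rangle^2}$ (the common
form; all averages are divide-by-$n$). Transitions among hierarchical
conformational substates on a given time scale cross many barriers of
similar height, so the spread of sampled energies is a reasonable proxy
for the height scale of those barriers — this justification is adopted,
not re-derived. With the Pearson correlation $r$ between the two
components over the same window,

$$\sigma_{tot}^2 \;=\; \sigma_p^2 + \sigma_{p\text{–}w}^2 +
  2\, r\, \sigma_p\, \sigma_{p\text{–}w}.$$

Because population moments are used throughout, this holds for every
window *exactly* (to round-off; the suite enforces $10^{-9}$ relative).
A divide-by-$(n-1)$ option exists (`sd()`-style estimates can be formed
from the returned $\sigma$ by rescaling) but population form is the
default precisely because it makes the identity exact.

Water *smooths* the protein's landscape in a window when
$\Delta\sigma = \sigma_{tot} - \sigma_p < 0$, which requires $r < 0$:
the hydration shell must energetically compensate the protein's
excursions. Each window is classified on the $(\Delta\sigma, r)$ plane:

* quadrant I — $\Delta\sigma \ge 0,\ r > 0$: roughening, reinforcing;
* quadrant IV — $\Delta\sigma \ge 0,\ r \le 0$: roughening despite
  anticorrelation (the slaving-like case);
* quadrant III — $\Delta\sigma < 0,\ r < 0$: smoothing;
* quadrant II — $\Delta\sigma < 0,\ r \ge 0$: algebraically impossible
  whenever $\sigma_{p\text{–}w} > 0$ (set $r \ge 0$ in the identity), so
  the package treats any such window as evidence of numerical corruption
  and fails loudly.

The axis orientation $(x = \Delta\sigma,\ y = r)$ is fixed by that
impossibility argument: it is the only orientation that makes the upper
left quadrant the empty one while keeping the common
$r<0,\ \Delta\sigma>0$ case in quadrant IV. Ties $\Delta\sigma = 0$ count
as roughening, matching the "larger than or equal to" convention used for
the roughening probability.

## Windowing

At each scale $\tau$ (an integer multiple of $\delta$), windows of
$n = 2^m$ points with stride $s = \tau/\delta$ are placed over the
trajectories:

* **Even deterministic placement.** "Uniformly distributed" is read as
  deterministic even spacing, not random placement: windows are allocated
  to trajectories proportionally to their admissible start ranges
  (largest-remainder apportionment, ties to earlier trajectories) and
  starts sit at $\mathrm{round}(i R / W)$ over the $R$ admissible starts.
  This makes window plans reproducible without any RNG; a seeded random
  mode is available for sensitivity checks. Windows may overlap — at fine
  scales even coverage requires it — and never span trajectory
  boundaries.
* **Exponent $m$.** Default analyses run $m = 5$ and $m = 6$ (32- and
  64-point windows) side by side, and `compare_exponents()` tabulates the
  discrepancy, because a larger $m$ would mix neighbouring time scales
  while conclusions should not depend on the choice within that range.
* **Budget.** `max_windows = 1000` per scale is an analysis choice (the
  per-scale window budget of the original analyses is not recoverable);
  1000 windows put the Monte-Carlo error of a mean $r$ near
  $0.3/\sqrt{1000} \approx 0.01$, well below the effects of interest.
* Scales the data cannot support are skipped with a logged warning rather
  than failing the run, so short series still exercise the full pipeline.

## The synthetic generator and its oracles

MD energy decompositions at this scale are not practical to regenerate,
so the package ships a first-class synthetic generator used by every
test. It emulates exactly three features of real energy fluctuations:
a *hierarchy of relaxation times* (femtosecond-to-nanosecond analogues),
*per-component amplitudes* with $\sigma(E_{p\text{–}w})$ able to exceed
$\sigma(E_p)$, and *tunable (typically negative) cross-correlation*. Each
component $k$ is a pair of independent unit-variance stationary
Ornstein–Uhlenbeck (OU) processes $X_k, Y_k$ with relaxation time
$\theta_k$, advanced by the exact discretisation
$X(t+\delta) = e^{-\delta/\theta_k} X(t) +
\sqrt{1 - e^{-2\delta/\theta_k}}\,\xi$, started from the stationary
distribution (so no burn-in is needed and closed forms hold from frame
one), and mixed as

$$E_p = \mu_p + \sum_k a_k X_k, \qquad
  E_{p\text{–}w} = \mu_w + \sum_k b_k\left(\rho_k X_k +
  \sqrt{1-\rho_k^2}\, Y_k\right).$$

The OU mixture is a testing stand-in, not a claim about any protein: real
energy series are neither Gaussian at every scale nor exactly
exponentially correlated, no attempt is made to reproduce the absolute
energy magnitudes of any real protein or force field,
and time units are abstract (the analysis depends only on ratios
$\tau/\delta$). What the mixture buys is *exact oracles*: stationary
variances $\sum a_k^2$, $\sum b_k^2$, covariance $\sum \rho_k a_k b_k$,
and — through `expected_window_variance()` — the exact expectation of a
windowed population variance under autocorrelation,
$E[s^2] = v\,(1 - n^{-2}\sum_{i,j} e^{-|i-j|\,s/\theta})$. Passing tests
therefore demonstrate that the *estimators* are correct, not that real
proteins behave like OU mixtures.

### What the windowed estimators can and cannot recover

One genuine statistical subtlety deserves prominence. The windowed sample
correlation is attenuated toward zero when the window *span*
$(n-1)\tau$ is short compared with the relaxation time of the dominant
component: the points inside such a window are strongly mutually
correlated and carry far fewer than $n$ effective degrees of freedom. For
a single component with $\theta = 10^3\,\delta$, $\rho = -0.6$ and
64-point windows at $\tau = \delta$, the mean windowed $r$ converges to
about $-0.55$, not $-0.6$, no matter how many windows are averaged; with
$\theta = 10\,\delta$ the attenuation is within $0.02$. This is a
property of windowed Pearson estimates in general — it applies equally to
windows cut from MD data — and is why the anticorrelation-recovery test
uses $\theta = 10\,\delta$ while the windowed-*variance* checks use the
autocorrelation-aware oracle above at any $\theta$. Mean windowed $r$
values at scales far below the slowest relaxation in the data should be
read as lower bounds on the magnitude of the underlying correlation.

## Numerical choices

* Two-pass centred moments everywhere ($10^{-12}$-level agreement with a
  naive loop is enforced); $\sigma$ clipped at zero against negative
  round-off; $r$ clamped to $[-1, 1]$.
* $r$ is *undefined* (an `NA` flag, never a number) when either window
  has zero variance. Undefined-$r$ windows are excluded from $r$ means,
  histograms and quadrant tallies but *kept* in $\sigma$ means and in the
  roughening/smoothing probabilities, which remain well defined; because
  the two averaging populations differ, summaries report $\sigma$ means
  over both (`mean_sigma_*` and `mean_sigma_*_defined`). Whether pooled
  or per-trajectory distributions are wanted is a user choice; pooling
  across trajectories is the default.
* Histograms use 50 equal-width bins spanning the observed range, last
  bin right-inclusive (binning is an analysis choice, not inherited).
* Determinism is a contract: identical configurations (including seeds)
  produce byte-identical TSV/JSON outputs, and the run manifest records a
  hash of the analytical configuration (output paths excluded).

## A worked synthetic example

A fast weakly coupled component plus a slow, water-dominated,
anticorrelated one reproduce the qualitative multi-scale signature of
hydration: correlation strengthening with $\tau$, roughness growing with
$\tau$, and $\sigma_{tot}$ dropping from above both components to between
them as $|r|$ grows.

```{r example}
model <- synthetic_model(
  rbind(ou_component(theta = 2,    a = 1,   b = 1,   rho = 0),
        ou_component(theta = 2000, a = 0.5, b = 2.5, rho = -0.9)),
  n_steps = 2e5, seed = 42
)
model_moments(model)

series <- simulate_series(model)
report <- analyze_landscape(series, scales = c(1, 8, 64, 512),
                            m = c(5, 6), max_windows = 1000)
tidy(report) |>
  filter(m == 6) |>
  select(tau, mean_r, mean_sigma_p, mean_sigma_pw, mean_sigma_tot,
         p_rough, p_smooth)
```

```{r figures, fig.show = "hold"}
autoplot(report, "correlation")
autoplot(report, "roughness")
autoplot(report, "quadrants")
```

The problem sizes used throughout the package's tests ($2\times10^5$-step
series, 1000–2000 windows per scale, up to six replicate seeds) were
chosen so that Monte-Carlo standard errors sit an order of magnitude
below every asserted tolerance.

## Limitations

* The NAMD-log reader sums *user-declared* column sets into $E_p$ and
  $E_{p\text{–}w}$; which force-field terms belong to each component
  (e.g. whether protein–ion terms join $E_p$) is left entirely to the
  user's mapping.
* No free energies, entropies or barrier heights are estimated; $\sigma$
  is a roughness proxy on each scale, nothing more.
* Analyses are meaningful up to spans the trajectories can support;
  milliseconds-and-longer domain motions and folding are out of scope.
* The generator shares one latent process per component between the two
  energies; real cross-correlation need not be scale-separable in this
  way. Conclusions drawn from synthetic runs are about the estimators.
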