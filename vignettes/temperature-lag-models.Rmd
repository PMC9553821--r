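---
title: "Distributed-lag models for temperature and daily injury counts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed-lag models for temperature and daily injury counts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatlag)
```

## The problem

Daily counts of weather-sensitive events — here, medical attendances after
motorcycle crashes in an arid-climate city — respond to ambient temperature
nonlinearly (risk rises at both cold and hot extremes) and with delay (an
exposure today can shift risk over the following days). `heatlag`
implements the standard epidemiological machinery for this setting:
a distributed-lag nonlinear model (DLNM) fitted by quasi-Poisson
regression, centered relative risks against the minimum-risk temperature,
attributable burden with Monte Carlo intervals, added heat-wave effects,
and thermal-stress indices — together with a synthetic generator whose
ground truth is known in closed form, so every stage can be validated
end to end.

## Model

For daily counts $Y_t$ with exposure series $x_t$ (a temperature or a
thermal index), the model is

$$
Y_t \sim \text{quasiPoisson}(\mu_t), \qquad
\log \mu_t = \alpha + \sum_{j,k} \theta_{jk} \, c_{jk}(t) + \text{confounders}_t,
$$

where the cross-basis entries
$c_{jk}(t) = \sum_{l=0}^{L} v_j(x_{t-l}) \, w_k(l)$
combine an exposure-dimension natural cubic spline $v$ (6 df by default)
with a lag-dimension natural cubic spline $w$ evaluated on the integer lag
grid $0..L$ (3 df including the constant, $L = 3$ days). Confounders are a
long-term/seasonal trend spline (7 df per calendar year, total
$\mathrm{round}(7 \times \text{years})$), day-of-week and holiday
indicators, 3-df splines of precipitation and wind, optionally a 3-df
spline of mean relative humidity, and optionally dummies for a 5-level
dust-visibility code. When the exposure is Humidex or WBGT the humidity
spline is dropped automatically: those indices already contain humidity
and retaining it would introduce collinearity.

The lag basis is deliberately near-saturated (3 df on 4 lag points); this
is the configuration of interest, not an accident, and it behaves well
because the lag dimension is tiny.

### Quasi-Poisson fitting

`fit_quasipoisson()` solves the Poisson score equations by IRLS with
step-halving, iterating to a relative deviance change below $10^{-10}$
(at most 100 iterations). The dispersion $\hat\phi$ is the Pearson
statistic over the residual degrees of freedom, and the coefficient
covariance is $\hat\phi (X^\top W X)^{-1}$ at the converged weights. The
test suite checks the fitter against both a free-standing Newton–Raphson
oracle and `stats::glm(family = quasipoisson())`; agreement is at the
$10^{-8}$ level for coefficients (differences beyond that reflect the two
implementations' different convergence criteria).

Degrees of freedom can be selected by generalized cross-validation,
$\mathrm{GCV} = n D / (n - p)^2$; `select_df_by_gcv()` scans each df axis
independently holding the others at their defaults (the joint grid is
rarely worth its cost at these sizes) and breaks ties toward the smaller
df.

### Centered risks and the minimum-risk temperature

All relative risks are contrasts against the minimum-risk temperature
(MMT). The lag-specific log-RR at exposure $x$ and lag $l$ is
$\sum_{jk} [v_j(x) - v_j(c)] \, w_k(l) \, \theta_{jk}$ and the cumulative
(lag 0–3) log-RR is its sum over lags, so the cumulative RR is exactly the
product of the per-lag RRs. Pointwise intervals come from the delta method
on the log scale ($z = 1.96$).

`find_mmt()` minimizes the cumulative curve on a 0.1-degree grid spanning
the 1st–99th percentile window of the observed exposures (the window
guards against boundary noise; the grid step is far below any
interpretable temperature difference). Its uncertainty interval follows
the simulation approach: 1000 multivariate-normal draws of the
cross-basis coefficients, re-minimizing per draw, reporting the
2.5th/97.5th percentiles. A numerically flat curve (all contrasts below
$10^{-12}$) is flagged degenerate and reported at the window midpoint.

Percentile contrasts use the 1st, 25th, 75th and 99th percentiles of the
exposure distribution, labelled extremely cold, cold, hot and extremely
hot; percentiles are computed by linear interpolation between order
statistics throughout the package.

### Attributable burden

The backward-perspective attributable fraction on day $t$ is

$$
\mathrm{AF}_t = 1 - \exp\Big(- \sum_{l=0}^{L} b(x_{t-l},\, l)\Big),
\qquad \mathrm{AN}_t = \mathrm{AF}_t \, Y_t,
$$

with $b(x, l)$ the MMT-centered lag-specific log-RR contribution. Cold and
heat components zero the contributions of lagged exposures on the other
side of the MMT *before* the AF transform; this makes the decomposition
exactly additive whenever each day's contributions are single-signed, and
additive to first order otherwise. Empirical 95% intervals re-evaluate the
totals over 1000 coefficient draws (Cholesky factorization, fixed seed;
a rank-deficient covariance is handled by pivoted Cholesky, and an
indefinite one is rejected after a logged eigenvalue floor of $10^{-12}$).
The MMT is held fixed across draws by default — the conventional choice
for attributable-burden intervals — with per-draw re-minimization
available behind `resample_mmt = TRUE`.

### Heat waves

A heat wave is a run of at least `min_duration` consecutive days on which
a metric strictly exceeds a threshold (strict `>`, matching the usual
"above the 99th percentile" phrasing); all days of a qualifying run are
flagged. The shipped catalog crosses metrics
{tmin, tmean, tmax, daytime apparent temperature} with
{>90th, >95th, >99th percentile for ≥2 days; >35 °C for ≥1 day} — sixteen
definitions spanning the stringency range from a handful of flagged days
to several hundred. It lives in `inst/extdata/heatwave_catalog.json` so an
alternative list can be dropped in without code changes. The added effect
of a definition is estimated by refitting the main model with the
indicator entered as unconstrained lag strata 0–3 and reporting
$e^{\beta_0}$ and $e^{\sum_l \beta_l}$ with delta-method intervals; a
definition that flags no days is an explicit error rather than a silent
zero row.

### Thermal indices

Vapor pressure is $(RH/100) \, e_s(T)$ with the Magnus saturation curve
$e_s(T) = 6.112 \exp(17.67\,T/(T+243.5))$ hPa (accurate to ~0.3% over
−40..50 °C). Humidex is $T + 0.5555\,(vp - 10)$ with $vp$ in hPa. WBGT
uses the radiation-free two-variable approximation
$0.567\,T + 0.393\,vp + 3.94$ with $vp$ in mmHg (1 mmHg = 1.333224 hPa,
converted internally so callers pass hPa everywhere); a multiplicative
variant of this formula circulates in print but yields physically absurd
values (hundreds of degrees), so the additive form is the default and the
literal product is retained only behind `form = "literal_product"` for
audit. Apparent temperature is $T + 0.33\,vp - 0.70\,v - 4.00$ (wind in
m/s); effective temperature is the Missenard form
$T - 0.4(T-10)(1 - RH/100)$, and net effective temperature its
wind-corrected extension. The apparent/effective/net-effective formulas
are standard published forms rather than any single study's supplementary
definitions, and their outputs carry a `provisional` flag to make that
explicit.

## The synthetic generator

`simulate_weather()` produces an arid-climate city: mean temperature is an
annual sinusoid (mean 19 °C, amplitude 13 °C, warm peak in mid-July) plus
AR(1) noise (coefficient 0.7, innovation SD 1.8 °C); a ~13 °C diurnal
range splits it into tmin/tmax, so realized extremes span roughly −10 to
+46 °C across the series; relative humidity is a clipped linear function
of temperature (anticorrelated, mean ≈ 37%); wind is gamma (mean
10.1 km/h) and precipitation zero-inflated gamma (mean 0.5 mm/day);
holidays are Bernoulli at 7% and the visibility code mostly 0. These
values were fixed once to match the descriptive climate of a
desert-margin Iranian city and are not tuning knobs.

`simulate_counts()` uses a piecewise-linear V-shaped cumulative
temperature effect — vertex 13.8 °C, cold slope 0.0289 and heat slope
0.0221 log-RR per degree, distributed over lags 0–3 with weights
(0.50, 0.24, 0.12, 0.14) — plus a baseline of log 15.8 events/day, a
0.14/year trend, small day-of-week offsets, a −0.05 holiday offset, and
negative-binomial counts with variance 1.3 × mean. The V-shape is
piecewise linear *on purpose*: the truth then has a closed form
(`true_cumulative_rr()`, `true_attributable_number()`) that is independent
of the estimator's spline basis, so recovery tests never test the code
against itself.

What the generator does **not** emulate: measurement error in exposures,
missing days, reporting artifacts (weekday batching of registrations),
exposure–confounder interactions, autocorrelated count residuals beyond
what the trend spline absorbs, and real holiday calendars (holidays are
random dates). Passing recovery tests therefore demonstrates that the
estimator recovers the truth *under the model's own assumptions plus
realistic marginals*, not that any particular real-world dataset would be
free of confounding or data-quality problems.

## Numerical choices

* **Basis parameterization.** The natural cubic spline uses the classical
  truncated-power representation with the linear-tail constraints built
  in; columns are exactly linear beyond the boundary knots, so
  out-of-range prediction is linear extrapolation (and is warned).
  Interior knots sit at equally spaced quantiles; on zero-inflated
  covariates (precipitation) tied quantile knots fall back to quantiles of
  the distinct values, logged at the chatty level.
* **Raw-scale columns.** Truncated-power columns reach magnitudes of
  $10^4$–$10^5$ on temperature ranges; the IRLS solve is QR-based
  (never normal equations) and the covariance is reconstructed from the
  R factor with pivot handling, which keeps the conditioning harmless at
  these sizes.
* **Degenerate inputs.** Constant exposure series are rejected where
  percentiles or knots would degenerate; an all-zero holiday column (or
  any aliased column) is rejected with the offending columns named; a
  zero-count series flags the attributable fraction as undefined rather
  than dividing by zero.
* **Tie-breaks.** GCV ties break toward the smaller df; argmin ties on
  the MMT grid take the first (coldest) grid point.
* **Validation problem sizes.** The validation suite uses 2300-day
  series (the scale of a six-year daily study) with 50-seed recovery
  loops, 100-replicate null-calibration loops, and 500 outer replicates
  at 600 days for attribution-interval coverage; these sizes give
  Monte Carlo error comfortably below the tolerances they are checked
  against.

## Design decisions on genuinely open points

* The per-year trend df is converted to a total as
  `round(7 × years_elapsed)` — the rate is stated per year, the total must
  be an integer.
* "Relative humidity" as a covariate means daily *mean* RH.
* GCV selection is per-axis, not a joint grid.
* The Monte Carlo eCI holds the MMT fixed across draws (resampling it is
  available but changes the estimand of the interval).
* Cold/heat attribution splits by the side of the MMT each *lagged
  exposure* falls on, not by classifying whole days; this is what makes
  the printed-style decomposition (total = cold + heat) hold.
* Week structure carries no hard-coded weekend: day-of-week is the civil
  calendar and holiday semantics come entirely from the supplied list, so
  calendars with a Friday weekend are handled by the data, not the code.

## Known limitations

* **MMT-centered null calibration.** With a fixed centering value the
  delta-method intervals are calibrated almost exactly (the suite's
  fixed-center check covers at ~96%). Centering at the *estimated* MMT,
  however, contrasts each exposure against the minimum of a noisy curve;
  under a null process this argmin selection inflates the contrast, and
  the suite's null-calibration experiment observes coverage of about
  91/100 instead of the nominal 95. This is a property of the
  centered-at-argmin procedure itself — narrowing the search window does
  not remove it — and users should read extreme-percentile RRs near the
  null accordingly.
* The added-effect model enters the heat-wave indicator as plain lag
  strata; it does not decompose main versus added effects beyond that
  single indicator.
* No penalized DLNM: df are fixed or grid-selected.
* Attribution is backward-perspective only.

## Reproducibility

Every stochastic stage (weather, counts, MMT draws, attribution draws)
takes an explicit seed and is byte-stable under it; `run_full_analysis()`
records the seed, a config hash and the package version in its manifest,
which suffices to regenerate every output identically.
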