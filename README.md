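# heatlag

Time-series analysis of extreme environmental temperature and daily injury
counts, built for the epidemiology of weather-sensitive events such as
motorcycle-crash medical attendances: people on two wheels are exposed to
the ambient air directly, so both cold snaps and heat extremes plausibly
move daily crash risk, with effects spread over several days.

`heatlag` provides, as tested R functions:

* **Distributed-lag nonlinear models (DLNM).** Daily counts
  $Y_t$ are modelled by quasi-Poisson regression with
  $\log \mu_t = \alpha + \sum_{j,k}\theta_{jk}\sum_{l=0}^{L} v_j(x_{t-l})\,w_k(l) + \text{confounders}$,
  where $v$ is a 6-df natural cubic spline in the exposure, $w$ a 3-df
  spline over lags $0..L$ ($L = 3$ days), and the confounders are a
  seasonal/long-term trend spline (7 df/year), day-of-week and holiday
  indicators, and splines of precipitation, wind and (optionally) relative
  humidity. Degrees of freedom can be selected by GCV.
* **Centered risks.** Relative risks against the minimum-risk temperature
  (MMT), found on a fine grid with a simulation-based confidence interval;
  lag-specific and cumulative (lag 0–3) RRs at the 1st/25th/75th/99th
  exposure percentiles ("extremely cold" … "extremely hot").
* **Attributable burden.** Backward-perspective attributable fraction
  $\mathrm{AF}_t = 1-\exp(-\sum_l b(x_{t-l},l))$ and number
  $\mathrm{AN}_t = \mathrm{AF}_t Y_t$, split into cold and heat
  components, with Monte Carlo empirical 95% intervals (1000 coefficient
  draws).
* **Heat waves.** A sixteen-definition catalog (metric × threshold ×
  duration), run-length detection, and added-effect models entering the
  heat-wave indicator as lag strata on top of the smooth temperature term.
* **Thermal indices.** Humidex, WBGT (two-variable approximation),
  apparent/effective/net-effective temperature, and the vapor-pressure
  helpers behind them.
* **A synthetic generator with closed-form ground truth** (seasonal AR(1)
  weather, V-shaped lag-distributed temperature effect, negative-binomial
  counts), so the whole pipeline is validated by parameter recovery rather
  than by fixtures.

## Worked example

```r
library(heatlag)

fx  <- generate_fixture("standard")          # 2300 synthetic days, known truth
fit <- fit_dlnm(fx$weather, fx$counts, model_spec(exposure = "tmean"))
fit
#> Quasi-Poisson DLNM fit
#>   n = 2297  p = 79  dispersion = 1.337  deviance = 2983.55
#>   exposure: tmean

mm <- find_mmt(fit, seed = 1)
sprintf("MMT: %.1f C (95%% CI %.1f, %.1f)", mm$mmt, mm$ci[1], mm$ci[2])
#> "MMT: 14.7 C (95% CI 13.7, 16.7)"

subset(rr_at_percentiles(fit, mmt = mm$mmt), lag == "lag03")
#>             label percentile exposure   lag   rr ci_low ci_high
#>    extremely cold          1      3.1 lag03 1.40   1.28    1.53
#>              cold         25     10.9 lag03 1.08   1.04    1.12
#>               hot         75     27.7 lag03 1.25   1.12    1.38
#>     extremely hot         99     35.7 lag03 1.51   1.33    1.71

attribute_burden(fit, mm$mmt, seed = 1)
#>   component    an an_low an_high     af af_low af_high
#> 1     total 11529   8173   14469 0.1602 0.1135  0.2010
#> 2      cold  3390   2260    4428 0.0471 0.0314  0.0615
#> 3      heat  8139   4820   11032 0.1131 0.0670  0.1533
```

Reading the output: the fitted dispersion 1.34 reproduces the generator's
overdispersion of 1.3; the MMT of 14.7 °C sits next to the generator's
true vertex of 13.8 °C; the cumulative risk rises to RR 1.51 at the 99th
temperature percentile (truth at that exposure: 1.61); and about 16% of
all events are attributed to non-optimal temperature, most of it
heat-side — the V-shape's heat arm covers far more person-days than the
cold arm in this climate. `true_cumulative_rr()` and
`true_attributable_number()` give the closed-form truths these numbers
are validated against.

The heat-wave side:

```r
hw <- heatwave_table(fx$weather, fx$counts)   # 16 definitions, day counts + added RRs
```

A command-line wrapper over the same functions is in
`inst/scripts/heatlag.R`
(`simulate | indices | fit | predict | attribute | heatwave | run`).

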