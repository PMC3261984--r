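# ccdlnm

Distributed lag non-linear models (DLNMs) inside a time-stratified
case-crossover design, for estimating the non-linear and delayed effects of
daily temperature on cause-specific mortality.

City-level studies of temperature and mortality face two entangled
problems: the exposure–response curve is U-shaped (both cold and heat
kill), and the response is lagged — cold effects surface after several days
and persist for a week or more, while heat effects are acute and partly
reflect mortality displacement (deaths advanced by a few days, followed by
a deficit). `ccdlnm` is for environmental epidemiologists who want to fit
both features at once while controlling season and trend by design rather
than by smoothing.

## The model

Daily death counts `Y_t` are modelled as overdispersed Poisson with

    log μ_t = α + Σ_{j,k} β_jk Σ_l R_j(x_{t−l}) B_k(l)
            + ns(RH_t,3) + ns(PM10_t,3) + ns(SO2_t,3) + ns(NO2_t,3)
            + λ·Strata_t + η·DOW_t + υ·Holiday_t + δ·Influenza_t

where the double sum is the **cross-basis**: exposure-basis columns `R_j`
(natural cubic spline, default 5 df with knots at equal spacings of the
temperature range; or the double-threshold pair `max(c−x,0)`, `max(x−h,0)`)
crossed with lag-basis columns `B_k` (default 4 df: intercept plus a
natural cubic spline with knots at equal log-lag intervals, lags 0–27).
`Strata_t` are fixed disjoint windows (year × calendar month by default):
conditioning on them is the time-stratified case-crossover, equivalent to
stratum indicators in the Poisson model — an identity the package verifies
by also fitting the stratum-eliminated conditional likelihood. Dispersion
is estimated from the Pearson statistic; model and temperature-measure
selection uses `QAIC = −2·logLik + 2·φ̂·p`. Cold/hot thresholds for the
double-threshold form are selected by residual deviance over a grid
(classically −5…5 °C × 19…29 °C in 0.1 °C steps). Effects are reported as
relative-risk surfaces over temperature and lag, lag curves per 1 °C beyond
a threshold, and cumulative effects `100·(exp(Σ_l logRR_l) − 1)` over lag
windows with delta-method 95% CIs.

Because no suitable daily mortality series is publicly deposited, the
package includes a synthetic-data module (`scenario()`,
`simulate_series()`) generating 3-year-like series with configurable
embedded temperature–lag effects, used throughout the tests for
parameter-recovery, calibration and threshold-recovery studies.

## Worked example

```r
library(ccdlnm)

# a 3-year series with realistic moments and a known embedded effect
series <- simulate_series(scenario("tianjin_like", seed = 1))
sm <- summarize_series(series)
subset(sm$summary, variable %in% c("tmean", "nonaccidental"))
#>        variable  min p25 median  p75   max mean   sd
#>           tmean -8.7 2.9   12.2 22.7  35.5 12.8 10.8
#>   nonaccidental 22.0  48   57.0 66.0 102.0 57.1 12.9

# select cold/hot thresholds by residual deviance (coarse-to-fine search)
sr <- coarse_to_fine(series, cold_range = c(-5, 5), hot_range = c(19, 29),
                     coarse_step = 1, fine_step = 0.1)
c(sr$best$cold_threshold, sr$best$hot_threshold)
#> [1]  3.0 19.8

# refit the double-threshold DLNM at the selected pair and summarise
fit <- fit_ccdlnm(series, crossbasis_spec(sr$best, lag_spec(27L, 4L)))
cumulative_effect(fit, "per_degree_below_cold", c(0L, 18L))
#> Cumulative effect (per_degree_below_cold), lags 0-18: 3.23% (95% CI 1.34, 5.15) *
cumulative_effect(fit, "per_degree_above_hot", c(0L, 2L))
#> Cumulative effect (per_degree_above_hot), lags 0-2: 0.63% (95% CI -0.25, 1.51)
```

The cold estimate reads: each 1 °C below the selected cold threshold is
associated with a 3.2% increase in nonaccidental deaths accumulated over
lags 0–18, significant at the two-sided 5% level (the `*`). This fixture
embeds a delayed cold effect of about 2.9% per °C over that window, inside
the CI. The hot effect in this scenario is acute but followed by a
mortality deficit, so at 1,095 days the net signal is weak: the search
places the hot threshold low and the 0–2 day estimate is attenuated —
exactly the behaviour longer series (or stronger effects) resolve, as the
recovery studies in the test suite show at 3,000 days.

The spline-DLNM form, surfaces and slices:

```r
fit5 <- fit_ccdlnm(series, crossbasis_spec(spline_spec(5L), lag_spec(27L, 4L)))
surf <- predict_surface(fit5)            # RR over temperature × lag
overall_effect_curve(fit5)               # cumulative RR across temperature
compare_measures(series)                 # QAIC: tmax vs tmean vs tmin × form
compare_designs(series)                  # case-crossover vs 7 df/yr time spline
sensitivity_analysis(series, thresholds = sr$best)  # windows 30/28/21, lags 20/30
```

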