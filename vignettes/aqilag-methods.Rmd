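---
title: "Modelling lagged Air Quality Index effects on daily mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lagged Air Quality Index effects on daily mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqilag)
```

## The scientific problem

Short-term exposure to air pollution is associated with excess cardiovascular
and cerebrovascular mortality, and the association is both **nonlinear** in
the exposure and **lagged**: a polluted day raises the death rate not only
that day but over the following days. Single-pollutant analyses miss the
mixture nature of real exposure, so a composite index — the Air Quality Index
(AQI), the maximum of per-pollutant sub-indices — is often used as the
exposure of record. `aqilag` provides the full chain for this kind of
analysis: AQI construction from concentrations, distributed-lag nonlinear
Poisson modelling of daily death counts, and additive/multiplicative
interaction analysis between binary AQI and meteorological factors.

Because municipal mortality registries are rarely distributable, the package
also ships a seeded simulator that emulates the marginal behaviour of a
subtropical Chinese city (seven years, about 26 deaths per day, AQI mostly
below 100) with a fully known exposure-lag-response surface, so every stage
is testable offline with ground truth.

## AQI construction

Each pollutant's sub-index (IAQI) is a piecewise-linear interpolation between
standard breakpoints:

$$\mathrm{IAQI}_P \;=\; \frac{\mathrm{IAQI}_{Hi}-\mathrm{IAQI}_{Lo}}
{\mathrm{BP}_{Hi}-\mathrm{BP}_{Lo}}\,(C_P-\mathrm{BP}_{Lo})
\;+\;\mathrm{IAQI}_{Lo},
\qquad
\mathrm{AQI} = \max_P\,\mathrm{IAQI}_P .$$

The bundled breakpoint table is the Chinese national standard (GB 3095-2012
concentration limits, HJ 633-2012 index grid 0/50/100/150/200/300/400/500),
with 24-h averaging segments for PM~2.5~, PM~10~, SO~2~, NO~2~ and CO and the
8-h maximum for O~3~ (capped at index 300, as the standard prescribes; a 1-h
O~3~ scale is also shipped). Sub-indices are rounded **up** to integers — the
standard's convention — and concentrations above the last breakpoint return
the top index with an overflow flag rather than extrapolating. Alternative
national tables can be supplied as a CSV with the same columns; only the
Chinese table ships as a default.

```{r aqi}
bp <- aqi_breakpoints()
compute_aqi(c(pm25 = 53, o3 = 120, no2 = 30), bp)
```

## Phase 1: the distributed-lag nonlinear model

Daily death counts are rare-event counts, modelled as
$Y_t \sim \mathrm{Poisson}(\mu_t)$ with

$$\log \mu_t = \alpha + cb(x_t, \ell) + ns(t,\ 7\times\text{years})
+ ns(\mathrm{Rh}_t, 3) + ns(\mathrm{WS}_t, 3) + \eta\,\mathrm{DOW}_t
+ \gamma\,\mathrm{Holiday}_t$$

where $cb(x_t,\ell)$ is the AQI **cross-basis**: the tensor product of an
exposure-dimension basis $f_\mathrm{var}$ and a lag-dimension basis
$f_\mathrm{lag}$, summed over lags $\ell = 0..L$,

$$cb_t \;=\; \mathrm{vec}\!\left(\sum_{\ell=0}^{L}
\big[f_\mathrm{var}(x_{t-\ell}) - f_\mathrm{var}(x_0)\big]
\otimes f_\mathrm{lag}(\ell)\right).$$

Centering the exposure basis at the reference $x_0$ pins $\mathrm{RR}(x_0)=1$
exactly. Two model presets are provided, mirroring the two published variants
of this model family: `"gam_eq"` (the default, above) and `"dlnm_eq"`, which
replaces the humidity/wind splines with 3x3-df cross-bases of pressure and
wind. Both are fitted by the same engine; nothing in the package decides
which variant is "right" — they are configuration, and an `aic_scan()` helper
ranks candidate degrees of freedom on the same retained rows.

Key conventions and defaults:

* **Lag window** $L = 7$ days; RR tables report single-day lags
  `Lag0..Lag7` and cumulative lags `Lag00..Lag07`.
* **Reference exposure** $x_0$: the series median AQI. The evaluation
  exposure for RR tables defaults to the 90th percentile (a "high-AQI day"),
  reported per 1 AQI unit.
* **Exposure/lag df**: 3 and 3 (natural cubic splines; interior knots at
  equally spaced quantiles, boundary knots at the data range). The lag basis
  includes its intercept column so lag-constant effects stay representable;
  `lag_df = "indicator"` gives one coefficient per lag (an ordinary
  distributed-lag model), and `var_df = "linear"` a linear exposure term.
* **Time trend**: 7 df per year, years counted as days/365.25 rounded to the
  nearest integer (so a 2,557-day series is 7 years even though it contains
  two leap days).
* **DOW**: factor with Monday as reference (six dummy contrasts). The
  holiday indicator is user-supplied (default none) and is dropped from the
  design when constant, since a constant column would be collinear with the
  intercept.
* **Lag trimming**: the first $L$ rows lack complete exposure history and are
  dropped, never zero-filled; `n_used` is reported in each fit. Zero-filling
  would bias early-lag coefficients toward the null.
* **Fitting**: IRLS with relative deviance tolerance `1e-9`, at most 50
  iterations. Rank deficiency is a hard error naming the collinear blocks —
  silent column dropping would silently change the meaning of the cross-basis
  contrasts. Plain Poisson is the default; a quasi-Poisson flag rescales the
  covariance by the Pearson dispersion for sensitivity, since daily death
  counts are often overdispersed.
* **Counts are never imputed.** Meteorology and pollutant columns may be
  linearly interpolated across interior gaps behind an explicit flag.

Single-lag and cumulative relative risks at exposure $x$ come from contrast
vectors against the fitted coefficient block: the cumulative log-RR at lag
$k$ is by construction the sum of the single-lag log-RRs up to $k$ (the
package's one self-consistent convention; published tables in this literature
do not always satisfy it), and intervals use the quadratic form of the
contrast against the coefficient covariance.

```{r phase1}
s <- simulate_daily_series(n_days = 1200, seed = 1)
res <- run_phase1(s, phase1_config(strata = "total"))
head(format_rr_table(res$total$rr_table), 4)
```

The overall exposure-response curve (`exposure_response_curve()`) cumulates
the surface over all lags on an exposure grid; its argmin is the **turning
point** used downstream to dichotomize exposures.

## Phase 2: joint effects of AQI and meteorology

Exposures are dichotomized — AQI at 100 (the national good/polluted boundary;
the pipeline warns and suggests 80 when the polluted cell has fewer than 30
days, since series from clean cities are sparse above 100) and the
meteorological variable at its turning point (median fallback) — and the
unadjusted interaction model

$$\log\mu = \alpha + \beta_1 E_1 + \beta_2 E_2 + \gamma\,E_1E_2$$

is fitted by the same Poisson engine. Versus the doubly-unexposed cell,
$RR_{10}=e^{\beta_1}$, $RR_{01}=e^{\beta_2}$,
$RR_{11}=e^{\beta_1+\beta_2+\gamma}$, and the interaction measures are

$$\mathrm{IRR}=\frac{RR_{11}}{RR_{01}RR_{10}}=e^{\gamma},\qquad
\mathrm{RERI}=RR_{11}-RR_{10}-RR_{01}+1,\qquad
\mathrm{AP}=\frac{\mathrm{RERI}}{RR_{11}}.$$

The AP denominator is $RR_{11}$: under a Poisson log-link model there is no
odds ratio to distinguish from the rate ratio, and the identity
$\mathrm{AP}\cdot RR_{11} = \mathrm{RERI}$ is asserted in the tests. IRR
intervals are Wald intervals on $\gamma$; RERI and AP intervals use the delta
method on $(\beta_1,\beta_2,\gamma)$ with the fitted covariance (no CI method
is canonical in this literature; a day-resampling bootstrap would be the
obvious sensitivity check and the adjusted fit — adding trend and DOW — is
provided behind a flag). The verdict is *synergistic* when the RERI interval
lies above 0, *antagonistic* below 0, and *none* otherwise; the same calls
follow from the AP interval. Confounders are deliberately absent from the
default phase-2 model: the four-cell model is saturated in the exposures, and
the adjusted variant exists for sensitivity only.

## The synthetic-data generator

`simulate_weather_pollutants()` draws temperature (annual sinusoid + AR(1)
noise), beta-distributed humidity around 76%, log-normal wind around
2.2 m/s, and six pollutant series of the form
*seasonal base x dispersion factor x noise*, where the dispersion factor
falls with wind, rises mildly with humidity, and is driven by a shared AR(1)
"stagnation" component that keeps pollutants strongly cross-correlated, as
co-measured urban pollutants are. Each pollutant is median-rescaled to a
target marginal (PM~2.5~ 22, PM~10~ 42, NO~2~ 20, SO~2~ 7, O~3~ 58 µg/m³, CO
0.67 mg/m³), chosen so the composite AQI lands in the envelope the analysis
targets: median ≈ 44--45, mean ≈ 46, range well inside [10, 200], and about
a dozen days above 100 in seven years.

`simulate_deaths()` builds
$\log\mu_t = \text{baseline} + \text{seasonal} + \text{DOW} +
\text{holiday} + \sum_\ell s\,w_\ell\,(x_{t-\ell}-80)_+ \;(+\,\gamma E_1E_2)$
with baseline $\log(25.8)$ deaths/day, a hinge at AQI 80 (risk in this regime
rises only past 80), per-unit slope $s=0.0015$ distributed over lags 0--2
with weights 0.4/0.35/0.25, and an optional injected interaction. Sex strata
are **two independent Poisson channels whose sum defines the total** — this
keeps `male + female = total` exact while permitting sex-specific exposure
effects (needed for contrast simulations) — and age strata are binomial
thinning of the total (share 0.80 aged ≥65, a typical proportion for
cardiovascular deaths), so `ge65 + lt65 = total` is exact too. All
randomness flows from one seed; replicate $k$ of any harness uses
`seed + k`.

What the generator does **not** emulate: spatial station structure,
measurement error and missingness patterns of real monitoring networks,
pandemic-era regime shifts, pollutant-specific health effects (the simulated
risk acts through the composite AQI only), and real holiday calendars.
Passing recovery tests therefore demonstrates the estimators are correct
under the stated data-generating process, not that any particular city's
published estimates are right.

## Numerical and design choices

* The exposure basis freezes its knots and boundary at build time, so
  prediction re-evaluates the identical basis; exposures outside the observed
  range error unless extrapolation is requested explicitly.
* With `max_lag = 0` the lag basis collapses to a constant and the
  cross-basis reduces to the exposure basis alone.
* Peak-lag summaries break ties toward the smallest lag.
* AIC is the Poisson deviance-based AIC ($-2\log\hat L + 2p$); candidates
  are comparable only on identical retained rows, enforced with an error.
* Pressure is stored verbatim in hPa (values near 1000); published tables in
  this area sometimes print "Pa" for the same values.
* Simulation sizes in the test-suite recovery studies (200 replicates of
  2,557-day series for surface recovery and null calibration, 500 for
  interaction recovery, 1,000 saturated 2x2 tables for type-I error) were
  chosen to make Monte-Carlo error small relative to the tolerances asserted,
  at about a minute of compute per study.
* The interaction recovery study dichotomizes AQI at its median rather than
  at 100: published interval widths for this analysis type (IRR CIs of width
  ≈ 0.06) imply thousands of deaths in the exposed cells, which a
  clean-city AQI distribution only yields under a median split. Under a split
  at 100 the same estimator remains unbiased but the verdict call is
  underpowered at realistic event counts.

## Limitations

Fixed-df regression splines only (no penalized DLNMs); no negative-binomial
or autocorrelation-robust variants; the composite AQI cannot attribute risk
to individual pollutants; and cross-basis conclusions at extreme exposures
rest on few days, as in any single-city series. The phase-2 model treats
days as independent given the covariates, which understates uncertainty when
counts are serially correlated beyond what the trend terms capture — the
quasi-Poisson flag and the adjusted interaction fit are the built-in
sensitivity checks.
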