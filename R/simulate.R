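#' Ground truth for the synthetic daily series
#'
#' Parameterizes the data-generating process: per-stratum baseline mortality,
#' seasonality, day-of-week and holiday effects, the exposure-lag-response
#' surface (a hinge in AQI above `threshold`, with the per-unit log-RR `slope`
#' distributed over lags by `lag_weights`), and an optional multiplicative
#' interaction between binary AQI and a meteorological variable.
#'
#' Defaults emulate the subtropical-city series the package targets: mean
#' daily total deaths 25.8, male share 53.3%, risk rising once AQI exceeds 80
#' with the effect concentrated on lags 0-2.
#'
#' @param baseline_log_mean log of the mean daily total death count.
#' @param seasonal_amplitude log-scale amplitude of the winter mortality
#'   excess.
#' @param dow_effects six log-scale offsets (Tue..Sun vs Monday).
#' @param holiday_effect log-scale holiday offset.
#' @param slope per-AQI-unit log-RR above the hinge threshold (cumulative over
#'   all lags).
#' @param threshold hinge location on the AQI scale (0 gives a linear
#'   surface).
#' @param lag_weights non-negative weights distributing `slope` over lags
#'   `0..L`; normalized to sum to 1.
#' @param interaction_gamma log-IRR between binary AQI and `interaction_var`
#'   (`NULL` = no interaction term).
#' @param interaction_var meteorological column for the interaction.
#' @param interaction_aqi_threshold AQI split for the injected interaction.
#' @param male_share,ge65_share stratum proportions.
#' @param stratum_effect_scale multipliers on the exposure surface per sex
#'   channel, `c(male = 1, female = 1)`.
#' @return a `simulation_truth` list.
#' @export
simulation_truth <- function(baseline_log_mean = log(25.8),
                             seasonal_amplitude = 0.06,
                             dow_effects = c(Tue = -0.005, Wed = -0.01,
                                             Thu = -0.005, Fri = 0,
                                             Sat = 0.01, Sun = 0.015),
                             holiday_effect = 0.02,
                             slope = 0.0015,
                             threshold = 80,
                             lag_weights = c(0.4, 0.35, 0.25, 0, 0, 0, 0, 0),
                             interaction_gamma = NULL,
                             interaction_var = "wind_mean",
                             interaction_aqi_threshold = 80,
                             male_share = 0.533,
                             ge65_share = 0.80,
                             stratum_effect_scale = c(male = 1, female = 1)) {
  stopifnot(all(lag_weights >= 0), length(dow_effects) == 6,
            male_share > 0, male_share < 1, ge65_share > 0, ge65_share < 1)
  if (sum(lag_weights) > 0) lag_weights <- lag_weights / sum(lag_weights)
  structure(list(baseline_log_mean = baseline_log_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 dow_effects = dow_effects, holiday_effect = holiday_effect,
                 slope = slope, threshold = threshold,
                 lag_weights = lag_weights,
                 interaction_gamma = interaction_gamma,
                 interaction_var = interaction_var,
                 interaction_aqi_threshold = interaction_aqi_threshold,
                 male_share = male_share, ge65_share = ge65_share,
                 stratum_effect_scale = stratum_effect_scale),
            class = "simulation_truth")
}

# day-of-year seasonal carrier: +1 mid-January, -1 mid-July
.seasonal <- function(t) cos(2 * pi * (t - 15) / 365.25)

.ar1 <- function(n, rho, sd) {
  e <- stats::rnorm(n, 0, sd)
  stats::filter(e, rho, method = "recursive") * sqrt(1 - rho^2)
}

# pollutant generator settings: target Table-style medians, winter/summer
# seasonality amplitude (log scale), wind coupling, humidity coupling
.pollutant_params <- data.frame(
  pollutant = c("pm25", "pm10", "no2", "so2", "o3", "co"),
  median = c(22, 42, 20, 7, 58, 0.67),
  seas_amp = c(0.30, 0.30, 0.25, 0.20, -0.35, 0.15),
  wind_coef = c(0.20, 0.20, 0.20, 0.18, 0.10, 0.15),
  hum_coef = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05)
)

#' Simulate daily meteorology and pollutant concentrations
#'
#' Temperature follows an annual sinusoid plus AR(1) noise; humidity is
#' beta-distributed around 76%; wind speed is log-normal around 2.2 m/s;
#' pollutant concentrations are a seasonal base times a dispersion factor that
#' decreases with wind and mildly increases with humidity, driven by a shared
#' AR(1) "stagnation" component plus small pollutant-specific noise, and
#' rescaled so each pollutant's sample median matches its target. The shared
#' component keeps pollutants strongly cross-correlated, as co-measured urban
#' pollutants are, so the composite AQI distribution stays in a realistic
#' envelope (median near 44, range within about 10-200).
#'
#' @param n_days number of days (>= 30).
#' @param seed RNG seed.
#' @param start first calendar date.
#' @param wind_coupling multiplier on the pollutant-wind coupling (0 removes
#'   the wind dependence).
#' @return data frame of date, meteorology and `conc_*` columns.
#' @export
simulate_weather_pollutants <- function(n_days, seed = 1,
                                        start = as.Date("2015-01-01"),
                                        wind_coupling = 1) {
  if (n_days < 30) stop("n_days must be >= 30")
  set.seed(seed)
  t <- seq_len(n_days)
  date <- start + t - 1
  seas <- .seasonal(t)
  temp_mean <- 22.9 - 9.5 * seas + as.numeric(.ar1(n_days, 0.65, 1.6))
  temp_min <- temp_mean - (3 + abs(stats::rnorm(n_days, 0, 1)))
  temp_max <- temp_mean + (4 + abs(stats::rnorm(n_days, 0, 1)))
  pressure <- 1000.7 + 8 * seas + stats::rnorm(n_days, 0, 2.5)
  humidity <- 100 * stats::rbeta(n_days, 0.763 * 20, 0.237 * 20)
  wind <- stats::rlnorm(n_days, log(2.171) - 0.45^2 / 2, 0.45)
  zw <- as.numeric(scale(log(wind)))
  zh <- as.numeric(scale(humidity))
  shared <- as.numeric(.ar1(n_days, 0.6, 0.25))
  out <- data.frame(date = date, pressure = pressure, temp_mean = temp_mean,
                    temp_min = temp_min, temp_max = temp_max,
                    wind_mean = wind, humidity_mean = humidity)
  for (i in seq_len(nrow(.pollutant_params))) {
    p <- .pollutant_params[i, ]
    lg <- p$seas_amp * seas - wind_coupling * p$wind_coef * zw +
      p$hum_coef * zh + shared + stats::rnorm(n_days, 0, 0.12)
    raw <- exp(lg)
    out[[paste0("conc_", p$pollutant)]] <- p$median * raw /
      stats::median(raw)
  }
  out
}

# true log-relative-rate contribution of the exposure surface on each day;
# exposure history before the series start is treated as at reference (zero)
.surface_term <- function(aqi, truth) {
  z <- pmax(aqi - truth$threshold, 0)
  L <- length(truth$lag_weights) - 1
  term <- rep(0, length(aqi))
  for (l in 0:L) {
    w <- truth$lag_weights[l + 1]
    if (w == 0) next
    zl <- c(rep(0, l), z[seq_len(length(z) - l)])
    term <- term + truth$slope * w * zl
  }
  term
}

#' Simulate daily death counts on top of a weather/pollutant series
#'
#' Builds `log mu_t = baseline + seasonal + DOW + holiday + surface(AQI
#' history) (+ gamma E1 E2)` and draws counts. Sex strata are two independent
#' Poisson channels (male share of the baseline, optionally channel-specific
#' exposure scaling) whose sum defines the total, so `male + female = total`
#' holds exactly; age strata arise by binomial thinning of the total, so
#' `ge65 + lt65 = total` holds exactly.
#'
#' @param series data frame with `date`, meteorology and an `aqi` column (run
#'   [add_aqi()] on [simulate_weather_pollutants()] output first).
#' @param truth a [simulation_truth()].
#' @param seed RNG seed for the count draws.
#' @return the series with `deaths_*`, `dow`, `holiday` columns, validated.
#' @export
simulate_deaths <- function(series, truth = simulation_truth(), seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!"aqi" %in% names(series)) stop("series needs an 'aqi' column")
  set.seed(seed)
  n <- nrow(series)
  if (!"dow" %in% names(series)) series <- add_calendar(series)
  t <- seq_len(n)
  lin <- truth$seasonal_amplitude * .seasonal(t) +
    c(0, truth$dow_effects)[as.integer(series$dow)] +
    truth$holiday_effect * series$holiday
  surf <- .surface_term(series$aqi, truth)
  if (!is.null(truth$interaction_gamma)) {
    met <- series[[truth$interaction_var]]
    E1 <- as.integer(series$aqi > truth$interaction_aqi_threshold)
    E2 <- as.integer(met > stats::median(met))
    lin <- lin + truth$interaction_gamma * E1 * E2
  }
  sc <- truth$stratum_effect_scale
  lp_male <- truth$baseline_log_mean + log(truth$male_share) + lin +
    sc[["male"]] * surf
  lp_female <- truth$baseline_log_mean + log(1 - truth$male_share) + lin +
    sc[["female"]] * surf
  if (any(exp(lp_male) > 1e6) || any(exp(lp_female) > 1e6)) {
    stop("simulated mean overflows (check slope/baseline)")
  }
  male <- stats::rpois(n, exp(lp_male))
  female <- stats::rpois(n, exp(lp_female))
  series$deaths_total <- male + female
  series$deaths_male <- male
  series$deaths_female <- female
  series$deaths_ge65 <- stats::rbinom(n, series$deaths_total,
                                      truth$ge65_share)
  series$deaths_lt65 <- series$deaths_total - series$deaths_ge65
  validate_daily_series(series)
}

#' One-call synthetic daily series
#'
#' Weather/pollutant simulation, AQI computation and mortality simulation in
#' sequence, all driven by one seed.
#'
#' @param n_days series length (default 2557, a 7-year daily grid).
#' @param seed RNG seed.
#' @param truth a [simulation_truth()].
#' @param ... passed to [simulate_weather_pollutants()].
#' @return a validated `daily_series`.
#' @export
simulate_daily_series <- function(n_days = 2557, seed = 1,
                                  truth = simulation_truth(), ...) {
  w <- simulate_weather_pollutants(n_days, seed = seed, ...)
  w <- add_aqi(w)
  simulate_deaths(w, truth = truth, seed = seed + 1000003L)
}
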