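#' Default phase-1 configuration
#'
#' Model presets mirror the two published model variants: `"gam_eq"` adjusts
#' for smooth time trend (7 df per year), natural splines of mean humidity and
#' mean wind speed (3 df each), day-of-week dummies and a holiday indicator;
#' `"dlnm_eq"` replaces the humidity/wind splines with cross-bases of pressure
#' and wind speed (3 df in each dimension). The AQI effect enters through a
#' cross-basis with the given exposure/lag df over lags `0..max_lag`.
#'
#' @param preset `"gam_eq"` (default) or `"dlnm_eq"`.
#' @param max_lag lag window L (default 7).
#' @param var_df exposure-dimension df for the AQI cross-basis (default 3);
#'   use `"linear"` for a linear exposure term.
#' @param lag_df lag-dimension df (default 3); use `"indicator"` for one
#'   coefficient per lag.
#' @param reference exposure pinned to RR 1 (`NULL` = series median AQI).
#' @param eval_x exposure at which RR tables are evaluated (`NULL` = 90th
#'   percentile of AQI, a "high-AQI day").
#' @param per report RRs per this exposure increment (default 1 AQI unit).
#' @param df_per_year trend df per year (default 7).
#' @param strata outcome columns to analyse.
#' @param family `"poisson"` or `"quasipoisson"`.
#' @return a `phase1_config` list.
#' @export
phase1_config <- function(preset = c("gam_eq", "dlnm_eq"), max_lag = 7,
                          var_df = 3, lag_df = 3, reference = NULL,
                          eval_x = NULL, per = 1, df_per_year = 7,
                          strata = c("total", "male", "female", "ge65",
                                     "lt65"),
                          family = "poisson") {
  structure(list(preset = match.arg(preset), max_lag = max_lag,
                 var_df = var_df, lag_df = lag_df, reference = reference,
                 eval_x = eval_x, per = per, df_per_year = df_per_year,
                 strata = strata, family = family),
            class = "phase1_config")
}

#' Assemble the phase-1 design matrix
#'
#' Binds intercept, the AQI cross-basis, the preset's confounder blocks,
#' day-of-week dummies (Monday reference) and the holiday indicator, recording
#' each block's column positions in the `block_index` attribute.
#'
#' @param series daily series with `aqi`, meteorology, `dow`, `holiday`.
#' @param cb the AQI [build_crossbasis()] matrix.
#' @param config a [phase1_config()].
#' @return design matrix with attribute `block_index`.
#' @export
assemble_design <- function(series, cb, config = phase1_config()) {
  n <- nrow(series)
  blocks <- list(intercept = matrix(1, n, 1, dimnames = list(NULL,
                                                             "(Intercept)")))
  blocks$cb <- unclass(cb)
  blocks$time <- time_trend_basis(series$date, config$df_per_year)
  colnames(blocks$time) <- paste0("time.", colnames(blocks$time))
  if (config$preset == "gam_eq") {
    blocks$humidity <- ns_basis(series$humidity_mean, spline_spec(df = 3))
    colnames(blocks$humidity) <- paste0("hum.", colnames(blocks$humidity))
    blocks$wind <- ns_basis(series$wind_mean, spline_spec(df = 3))
    colnames(blocks$wind) <- paste0("wind.", colnames(blocks$wind))
  } else {
    conf_cb <- function(v, nm) {
      b <- build_crossbasis(v, crossbasis_spec(var_spec = 3, lag_spec = 3,
                                               max_lag = config$max_lag))
      b <- unclass(b)
      colnames(b) <- paste0(nm, ".", colnames(b))
      b
    }
    blocks$pressure <- conf_cb(series$pressure, "press")
    blocks$wind <- conf_cb(series$wind_mean, "wind")
  }
  dm <- stats::model.matrix(~dow, data = series)[, -1, drop = FALSE]
  blocks$dow <- dm
  # a constant indicator (e.g. no holidays supplied) would be collinear with
  # the intercept; include the block only when it varies
  if (length(unique(series$holiday)) > 1) {
    blocks$holiday <- matrix(series$holiday, n, 1,
                             dimnames = list(NULL, "holiday"))
  }
  X <- do.call(cbind, blocks)
  pos <- cumsum(vapply(blocks, ncol, numeric(1)))
  start <- c(1, utils::head(pos, -1) + 1)
  attr(X, "block_index") <- stats::setNames(
    Map(function(a, b) seq(a, b), start, pos), names(blocks))
  X
}

.stratum_column <- function(stratum) {
  switch(stratum,
         total = "deaths_total", male = "deaths_male",
         female = "deaths_female", ge65 = "deaths_ge65",
         lt65 = "deaths_lt65",
         stop("unknown stratum: ", stratum))
}

#' Run the phase-1 lag analysis
#'
#' For each stratum: builds the AQI cross-basis, fits the preset Poisson
#' model on that stratum's counts, evaluates single-day and cumulative RRs at
#' the configured exposure for lags `0..L`, and extracts the peak-lag
#' summaries (ties break toward the smallest lag). Strata whose outcome column
#' is absent are skipped with a warning.
#'
#' @param series validated daily series with an `aqi` column (use [add_aqi()]
#'   first when only concentrations are present).
#' @param config a [phase1_config()].
#' @return named list of `stratum_result` lists (`stratum`, `fit`, `rr_table`,
#'   `max_single_lag`, `max_cumulative_lag`, `cb`), with the shared
#'   `eval_x`/`reference` recorded in attributes.
#' @export
run_phase1 <- function(series, config = phase1_config()) {
  if (!"aqi" %in% names(series)) {
    stop("series has no 'aqi' column; run add_aqi() first")
  }
  if (!"dow" %in% names(series)) series <- add_calendar(series)
  reference <- config$reference
  if (is.null(reference)) reference <- stats::median(series$aqi)
  eval_x <- config$eval_x
  if (is.null(eval_x)) {
    eval_x <- as.numeric(stats::quantile(series$aqi, 0.9, names = FALSE))
  }
  spec <- crossbasis_spec(var_spec = config$var_df, lag_spec = config$lag_df,
                          max_lag = config$max_lag, reference = reference)
  cb <- build_crossbasis(series$aqi, spec)
  X <- assemble_design(series, cb, config)
  out <- list()
  for (st in config$strata) {
    col <- .stratum_column(st)
    if (!col %in% names(series)) {
      warning("stratum '", st, "' skipped: column ", col, " absent")
      next
    }
    fit <- fit_poisson(series[[col]], X, family = config$family)
    rr <- predict_rr(fit, cb, eval_x, mode = "both")
    sing <- rr[rr$lag_kind == "single", ]
    cum <- rr[rr$lag_kind == "cumulative", ]
    pk <- function(tab) {
      i <- which.max(tab$rr)  # which.max takes the first (smallest lag) tie
      tab[i, c("lag", "rr", "lower95", "upper95")]
    }
    out[[st]] <- structure(list(stratum = st, fit = fit, rr_table = rr,
                                max_single_lag = pk(sing),
                                max_cumulative_lag = pk(cum), cb = cb),
                           class = "stratum_result")
  }
  attr(out, "eval_x") <- eval_x
  attr(out, "reference") <- reference
  out
}

#' Overall cumulative exposure-response curve
#'
#' Evaluates the lag-cumulated (over `0..L`) relative risk at each grid point
#' versus the cross-basis reference. The returned curve carries the turning
#' point — the grid argmin of the cumulative RR — used downstream to
#' dichotomize exposures.
#'
#' @param fit a [fit_poisson()] result.
#' @param cb the [build_crossbasis()] matrix from the same design.
#' @param grid exposure values (default: 100 points across the exposure range).
#' @param ... passed to [predict_rr()].
#' @return data frame (`x`, `rr`, `lower95`, `upper95`) with attribute
#'   `turning_point`.
#' @export
exposure_response_curve <- function(fit, cb, grid = NULL, ...) {
  if (is.null(grid)) {
    rng <- attr(cb, "range")
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  L <- attr(cb, "spec")$max_lag
  rows <- lapply(grid, function(x) {
    r <- predict_rr(fit, cb, x, mode = "cumulative", ...)
    r <- r[r$lag == L, ]
    data.frame(x = x, rr = r$rr, lower95 = r$lower95, upper95 = r$upper95)
  })
  out <- do.call(rbind, rows)
  attr(out, "turning_point") <- out$x[which.min(out$rr)]
  out
}

#' Serialize an RR table in the published layout
#'
#' Rows Lag0..LagL then Lag00..Lag0L (cumulative), columns RR and the 95%
#' interval.
#'
#' @param rr an `rr_table` from [predict_rr()].
#' @return data frame with a `lag_label` column.
#' @export
format_rr_table <- function(rr) {
  lab <- ifelse(rr$lag_kind == "single", paste0("Lag", rr$lag),
                paste0("Lag0", rr$lag))
  data.frame(lag_label = lab, rr = rr$rr, lower95 = rr$lower95,
             upper95 = rr$upper95)
}

#' Lag-effect diagnostic plot
#'
#' Single-day and cumulative RR by lag with 95% ribbons. Requires ggplot2.
#'
#' @param rr an `rr_table`.
#' @return a ggplot object.
#' @export
plot_lag_effects <- function(rr) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(rr, ggplot2::aes(x = lag, y = rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower95, ymax = upper95),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~lag_kind) +
    ggplot2::labs(x = "lag (days)", y = "relative risk")
}
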