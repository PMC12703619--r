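#' Dichotomize AQI and a meteorological variable
#'
#' Builds the 2x2 exposure classification used by the joint-effect analysis:
#' `E1 = 1` on polluted days (AQI above `aqi_threshold`; the national standard
#' splits at 100, good vs polluted) and `E2 = 1` on days where the
#' meteorological variable exceeds its turning point (the minimum of the
#' fitted exposure-response curve, or the median when no curve is available).
#' Estimation is refused when any exposure cell is empty; sparse polluted
#' cells (< 30 days) trigger a warning suggesting a lower threshold such as
#' 80.
#'
#' @param series daily series with `aqi` and the meteorological column.
#' @param met_var meteorological column name (e.g. `"wind_mean"`).
#' @param turning_point split value for `met_var`.
#' @param aqi_threshold AQI split (default 100).
#' @param outcome outcome count column (default `"deaths_total"`).
#' @return an `interaction_input` list: `y`, `E1`, `E2`, `cells` (2x2 day
#'   counts, rows E1, cols E2), `met_var`, thresholds.
#' @export
dichotomize <- function(series, met_var, turning_point, aqi_threshold = 100,
                        outcome = "deaths_total") {
  stopifnot(met_var %in% names(series), "aqi" %in% names(series),
            outcome %in% names(series))
  if (!is.finite(turning_point) || !is.finite(aqi_threshold)) {
    stop("thresholds must be finite")
  }
  E1 <- as.integer(series$aqi > aqi_threshold)
  E2 <- as.integer(series[[met_var]] > turning_point)
  cells <- table(factor(E1, levels = 0:1), factor(E2, levels = 0:1))
  cells <- matrix(as.integer(cells), 2, 2,
                  dimnames = list(E1 = 0:1, E2 = 0:1))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("exposure cell (E1=", empty[1] - 1, ", E2=", empty[2] - 1,
         ") is empty; try a lower aqi_threshold (e.g. 80)")
  }
  if (sum(cells[2, ]) < 30) {
    warning("only ", sum(cells[2, ]), " polluted days (AQI > ", aqi_threshold,
            "); estimates will be unstable - consider aqi_threshold = 80")
  }
  structure(list(y = series[[outcome]], E1 = E1, E2 = E2, cells = cells,
                 met_var = met_var, turning_point = turning_point,
                 aqi_threshold = aqi_threshold),
            class = "interaction_input")
}

#' Additive and multiplicative interaction between AQI and a meteorological
#' factor
#'
#' Fits `log mu = alpha + b1 E1 + b2 E2 + g E1 E2` by Poisson regression and
#' reports, versus the doubly-unexposed cell: `RR10 = exp(b1)`,
#' `RR01 = exp(b2)`, `RR11 = exp(b1 + b2 + g)`; the multiplicative interaction
#' `IRR = exp(g) = RR11 / (RR01 RR10)`; and the additive measures
#' `RERI = RR11 - RR10 - RR01 + 1` and `AP = RERI / RR11`. The IRR interval is
#' `exp(g +/- 1.96 SE(g))`; RERI and AP intervals come from the delta method
#' on `(b1, b2, g)` with the fitted covariance. The verdict is synergistic
#' when the RERI interval lies above 0, antagonistic when below 0, and none
#' otherwise. An `adjusted = TRUE` sensitivity fit adds the smooth time trend
#' and day-of-week dummies.
#'
#' @param input an [dichotomize()] result (or a list with `y`, `E1`, `E2`).
#' @param adjusted add trend + DOW confounders (needs `series`).
#' @param series the daily series (only for `adjusted = TRUE`).
#' @param df_per_year trend df per year for the adjusted fit.
#' @return an `interaction_result` list: `RR10`, `RR01`, `RR11` (each with
#'   CI), `IRR`, `RERI`, `AP` (each with CI), `verdict`, `cells`, `fit`.
#' @export
fit_interaction <- function(input, adjusted = FALSE, series = NULL,
                            df_per_year = 7) {
  y <- input$y
  E1 <- input$E1
  E2 <- input$E2
  stopifnot(all(E1 %in% 0:1), all(E2 %in% 0:1))
  n <- length(y)
  X <- cbind("(Intercept)" = 1, E1 = E1, E2 = E2, "E1:E2" = E1 * E2)
  bi <- list(intercept = 1L, E1 = 2L, E2 = 3L, interaction = 4L)
  if (adjusted) {
    if (is.null(series)) stop("adjusted = TRUE requires the series")
    if (!"dow" %in% names(series)) series <- add_calendar(series)
    tt <- time_trend_basis(series$date, df_per_year)
    colnames(tt) <- paste0("time.", colnames(tt))
    dm <- stats::model.matrix(~dow, data = series)[, -1, drop = FALSE]
    X <- cbind(X, tt, dm)
    bi$time <- 4L + seq_len(ncol(tt))
    bi$dow <- 4L + ncol(tt) + seq_len(ncol(dm))
  }
  attr(X, "block_index") <- bi
  fit <- fit_poisson(y, X)
  if (!fit$converged) stop("interaction model did not converge")
  b <- unname(fit$beta[2:4])
  V <- unname(fit$cov[2:4, 2:4])
  rr10 <- exp(b[1]); rr01 <- exp(b[2]); rr11 <- exp(sum(b))
  ci <- function(est, se) c(est - 1.96 * se, est + 1.96 * se)
  se_b1 <- sqrt(V[1, 1]); se_b2 <- sqrt(V[2, 2]); se_g <- sqrt(V[3, 3])
  a11 <- c(1, 1, 1)
  se_11 <- sqrt(as.numeric(a11 %*% V %*% a11))
  reri <- rr11 - rr10 - rr01 + 1
  ap <- reri / rr11
  # delta-method gradients on (b1, b2, g)
  g_reri <- c(rr11 - rr10, rr11 - rr01, rr11)
  se_reri <- sqrt(as.numeric(g_reri %*% V %*% g_reri))
  g_ap <- c(rr11 - rr10 - reri, rr11 - rr01 - reri, rr11 - reri) / rr11
  se_ap <- sqrt(as.numeric(g_ap %*% V %*% g_ap))
  reri_ci <- reri + c(-1.96, 1.96) * se_reri
  verdict <- if (reri_ci[1] > 0) "synergistic" else
    if (reri_ci[2] < 0) "antagonistic" else "none"
  structure(list(
    RR10 = c(est = unname(rr10), exp(ci(unname(b[1]), se_b1))),
    RR01 = c(est = unname(rr01), exp(ci(unname(b[2]), se_b2))),
    RR11 = c(est = unname(rr11), exp(ci(log(unname(rr11)), se_11))),
    IRR = c(est = exp(unname(b[3])), exp(ci(unname(b[3]), se_g))),
    RERI = c(est = reri, reri_ci),
    AP = c(est = ap, ap + c(-1.96, 1.96) * se_ap),
    verdict = verdict,
    cells = input$cells,
    fit = fit
  ), class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  f <- function(v) sprintf("%.5f (%.5f-%.5f)", v[1], v[2], v[3])
  cat("2x2 joint-effect analysis\n")
  cat("  IRR  ", f(x$IRR), "\n  RERI ", f(x$RERI), "\n  AP   ", f(x$AP), "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Joint-effect table across meteorological variables
#'
#' Runs [dichotomize()] + [fit_interaction()] for each listed variable and
#' returns one row per variable in the published layout: IRR, RERI and AP
#' with intervals, verdict, and the exposure-cell day counts.
#'
#' @param series daily series.
#' @param met_vars named numeric vector: variable name -> turning point.
#' @param aqi_threshold AQI split (default 100).
#' @param outcome outcome column.
#' @param ... passed to [fit_interaction()].
#' @return data frame, one row per meteorological variable, with the
#'   `interaction_result` objects in attribute `results`.
#' @export
run_phase2 <- function(series, met_vars, aqi_threshold = 100,
                       outcome = "deaths_total", ...) {
  res <- lapply(names(met_vars), function(v) {
    inp <- dichotomize(series, v, met_vars[[v]],
                       aqi_threshold = aqi_threshold, outcome = outcome)
    fit_interaction(inp, ...)
  })
  names(res) <- names(met_vars)
  row <- function(v) {
    r <- res[[v]]
    data.frame(variable = v,
               irr = r$IRR[1], irr_lo = r$IRR[2], irr_hi = r$IRR[3],
               reri = r$RERI[1], reri_lo = r$RERI[2], reri_hi = r$RERI[3],
               ap = r$AP[1], ap_lo = r$AP[2], ap_hi = r$AP[3],
               verdict = r$verdict,
               n00 = r$cells[1, 1], n01 = r$cells[1, 2],
               n10 = r$cells[2, 1], n11 = r$cells[2, 2], row.names = NULL)
  }
  out <- do.call(rbind, lapply(names(met_vars), row))
  attr(out, "results") <- res
  out
}
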