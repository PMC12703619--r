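#' Canonical daily time-series data model
#'
#' A `daily_series` is a data frame on a contiguous daily calendar grid holding
#' death counts (total plus sex and age strata), meteorology, pollutant
#' concentrations and/or a precomputed AQI, with derived calendar covariates
#' (`dow`, `holiday`). All downstream modelling functions consume this object.
#'
#' @name daily_series
#' @keywords internal
NULL

.count_cols <- c("deaths_total", "deaths_male", "deaths_female",
                 "deaths_ge65", "deaths_lt65")
.met_cols <- c("pressure", "temp_mean", "temp_min", "temp_max",
               "wind_mean", "humidity_mean")
.pollutants <- c("pm25", "pm10", "no2", "so2", "o3", "co")

#' Validate a daily series
#'
#' Checks the invariants of the canonical daily table: a strictly increasing
#' contiguous date grid, non-negative integer counts, stratum sums matching the
#' total wherever all components are present, humidity in \[0, 100\], wind
#' speed non-negative, and at least one exposure column (`aqi` or a pollutant
#' concentration) on every day.
#'
#' @param x data frame with a `date` column (`Date`).
#' @return `x` invisibly, with class `daily_series` prepended.
#' @export
validate_daily_series <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"date" %in% names(x)) stop("daily series must have a 'date' column")
  d <- as.Date(x$date)
  if (anyNA(d)) stop("unparseable dates at rows: ",
                     paste(which(is.na(d)), collapse = ", "))
  if (is.unsorted(d, strictly = TRUE)) {
    stop("dates must be strictly increasing with no duplicates")
  }
  full <- seq(d[1], d[length(d)], by = "day")
  if (length(full) != length(d)) {
    missing <- setdiff(as.character(full), as.character(d))
    stop("calendar gap: missing dates ", paste(missing, collapse = ", "))
  }
  for (cc in intersect(.count_cols, names(x))) {
    v <- x[[cc]]
    if (!is.numeric(v)) stop("count column '", cc, "' is not numeric")
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad)) {
      stop("count column '", cc, "' has negative or non-integer values on ",
           paste(as.character(d[bad[seq_len(min(5, length(bad)))]]),
                 collapse = ", "))
    }
  }
  chk_sum <- function(parts, lab) {
    if (all(c(parts, "deaths_total") %in% names(x))) {
      s <- x[[parts[1]]] + x[[parts[2]]]
      bad <- which(!is.na(s) & !is.na(x$deaths_total) & s != x$deaths_total)
      if (length(bad)) {
        stop(lab, " do not sum to deaths_total on ",
             paste(as.character(d[bad[seq_len(min(5, length(bad)))]]),
                   collapse = ", "))
      }
    }
  }
  chk_sum(c("deaths_male", "deaths_female"), "deaths_male + deaths_female")
  chk_sum(c("deaths_ge65", "deaths_lt65"), "deaths_ge65 + deaths_lt65")
  if ("humidity_mean" %in% names(x)) {
    h <- x$humidity_mean
    if (any(!is.na(h) & (h < 0 | h > 100))) {
      stop("humidity_mean must lie in [0, 100]")
    }
  }
  if ("wind_mean" %in% names(x) && any(!is.na(x$wind_mean) & x$wind_mean < 0)) {
    stop("wind_mean must be non-negative")
  }
  conc_cols <- paste0("conc_", .pollutants)
  have_exposure <- rep(FALSE, nrow(x))
  if ("aqi" %in% names(x)) have_exposure <- have_exposure | !is.na(x$aqi)
  for (cc in intersect(conc_cols, names(x))) {
    have_exposure <- have_exposure | !is.na(x[[cc]])
  }
  if (!all(have_exposure)) {
    stop("no exposure (aqi or pollutant concentration) on ",
         paste(as.character(d[which(!have_exposure)[seq_len(
           min(5, sum(!have_exposure)))]]), collapse = ", "))
  }
  x$date <- d
  class(x) <- unique(c("daily_series", class(x)))
  invisible(x)
}

#' Derive calendar covariates
#'
#' Adds `dow` (day-of-week factor with Monday as the reference level, so model
#' matrices encode six dummy contrasts against Monday) and a binary `holiday`
#' indicator joined from a user-supplied date list.
#'
#' @param x data frame with a `date` column.
#' @param holidays character or `Date` vector of holiday dates (default none).
#' @return `x` with `dow` and `holiday` columns.
#' @export
add_calendar <- function(x, holidays = character()) {
  d <- as.Date(x$date)
  lv <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  # ISO weekday: 1970-01-05 was a Monday
  x$dow <- factor(lv[(as.integer(d) - 4L) %% 7L + 1L], levels = lv)
  x$holiday <- as.integer(d %in% as.Date(holidays))
  x
}

#' Read a daily series from CSV
#'
#' Reads an RFC-4180 CSV with a header row, renames columns through
#' `column_map`, parses ISO-8601 dates, derives calendar covariates and
#' validates the result. Death counts are never imputed; meteorology and
#' pollutant columns may be linearly interpolated across interior gaps when
#' `interpolate = TRUE`.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping file column names to
#'   canonical names (`c(file_name = "canonical_name")`). Columns already
#'   canonically named need no entry.
#' @param holidays holiday date vector passed to [add_calendar()].
#' @param interpolate logical; interpolate missing meteorology/pollutant cells.
#' @return a validated `daily_series`.
#' @export
read_daily_series <- function(path, column_map = NULL, holidays = character(),
                              interpolate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(x))
    if (anyNA(idx)) {
      stop("column_map names not in file: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "))
    }
    names(x)[idx] <- unname(column_map)
  }
  if (!"date" %in% names(x)) stop("no 'date' column after mapping")
  file_holiday <- if ("holiday" %in% names(x)) x$holiday else NULL
  x$dow <- NULL  # always re-derived from the date
  num_cols <- setdiff(names(x), "date")
  for (cc in num_cols) {
    v <- x[[cc]]
    if (is.character(v)) {
      vv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "' at row ", bad[1])
      }
      x[[cc]] <- vv
    }
  }
  if (interpolate) {
    interp_cols <- intersect(c(.met_cols, paste0("conc_", .pollutants), "aqi"),
                             names(x))
    for (cc in interp_cols) {
      v <- x[[cc]]
      if (anyNA(v) && sum(!is.na(v)) >= 2) {
        x[[cc]] <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                                 xout = seq_along(v), rule = 1)$y
      }
    }
  }
  x <- add_calendar(x, holidays)
  if (!length(holidays) && !is.null(file_holiday)) {
    x$holiday <- as.integer(file_holiday)  # keep the indicator from the file
  }
  validate_daily_series(x)
}

#' Write a daily series to CSV
#'
#' Numeric fields are written with full precision (15 significant digits) so a
#' write/read round trip reproduces the series.
#'
#' @param x daily series.
#' @param path output CSV path.
#' @export
write_daily_series <- function(x, path) {
  y <- as.data.frame(x)
  y$date <- format(as.Date(y$date), "%Y-%m-%d")
  for (cc in names(y)) {
    if (is.numeric(y[[cc]]) && !all(y[[cc]] == round(y[[cc]]), na.rm = TRUE)) {
      # 17 significant digits guarantee an exact double round trip
      y[[cc]] <- sprintf("%.17g", y[[cc]])
    }
  }
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Matrix of lagged copies of a series
#'
#' Column `k + 1` holds the series shifted by `k` days: the value in row `t`
#' is `x[t - k]`. The first `max_lag` rows have incomplete lagged history;
#' their missing entries are `NA` and the attribute `incomplete` flags those
#' rows so fitting can drop them.
#'
#' @param x numeric vector.
#' @param max_lag maximum lag (integer >= 0, less than `length(x)`).
#' @return an `n x (max_lag + 1)` matrix with columns `lag0 ... lag<max_lag>`
#'   and a logical attribute `incomplete` of length `n`.
#' @export
lag_matrix <- function(x, max_lag) {
  n <- length(x)
  stopifnot(max_lag >= 0, max_lag == round(max_lag))
  if (max_lag >= n) stop("max_lag (", max_lag, ") must be < series length (",
                         n, ")")
  m <- vapply(0:max_lag, function(k) c(rep(NA_real_, k), x[seq_len(n - k)]),
              numeric(n))
  m <- matrix(m, nrow = n,
              dimnames = list(NULL, paste0("lag", 0:max_lag)))
  attr(m, "incomplete") <- seq_len(n) <= max_lag
  m
}
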