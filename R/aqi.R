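#' AQI breakpoint table
#'
#' Loads a per-pollutant breakpoint table for piecewise-linear sub-index
#' computation. The default table ships the Chinese national standard
#' (GB 3095-2012 concentration limits with HJ 633-2012 index breakpoints):
#' 24-h averaging segments for PM2.5, PM10, SO2, NO2 and CO, the 8-h maximum
#' for O3 (`"o3"`, capped at index 300 per the standard) and a 1-h O3 option
#' (`"o3_1h"`). Alternative national tables can be supplied as a CSV with the
#' same columns.
#'
#' @param path CSV with columns `pollutant, avg_period, bp_lo, bp_hi,
#'   iaqi_lo, iaqi_hi`; default is the bundled Chinese standard.
#' @return a `breakpoint_table`: data frame of validated, contiguous segments.
#' @export
aqi_breakpoints <- function(path = system.file("extdata",
                                               "aqi_breakpoints_cn.csv",
                                               package = "aqilag")) {
  bp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pollutant", "avg_period", "bp_lo", "bp_hi", "iaqi_lo", "iaqi_hi")
  stopifnot(all(need %in% names(bp)))
  for (p in unique(bp$pollutant)) {
    seg <- bp[bp$pollutant == p, ]
    seg <- seg[order(seg$bp_lo), ]
    if (any(seg$bp_lo >= seg$bp_hi) || any(seg$iaqi_lo >= seg$iaqi_hi)) {
      stop("degenerate segment for pollutant ", p)
    }
    k <- nrow(seg)
    if (k > 1 && (any(seg$bp_hi[-k] != seg$bp_lo[-1]) ||
                  any(seg$iaqi_hi[-k] != seg$iaqi_lo[-1]))) {
      stop("non-contiguous segments for pollutant ", p)
    }
  }
  class(bp) <- c("breakpoint_table", class(bp))
  bp
}

#' Individual air-quality sub-index (IAQI)
#'
#' Piecewise-linear interpolation of a pollutant concentration onto the index
#' scale: within the segment with `bp_lo <= c <= bp_hi`,
#' `IAQI = (iaqi_hi - iaqi_lo) / (bp_hi - bp_lo) * (c - bp_lo) + iaqi_lo`,
#' rounded up to the nearest integer (the standard's convention; disable with
#' `round_up = FALSE`). Concentrations above the table's last segment return
#' the pollutant's top index with attribute `overflow = TRUE` rather than
#' extrapolating.
#'
#' @param conc concentration(s), ug/m3 (mg/m3 for CO); vectorised.
#' @param pollutant pollutant id present in `table` (e.g. `"pm25"`).
#' @param table a [aqi_breakpoints()] table.
#' @param round_up round the sub-index up to an integer (default TRUE).
#' @return numeric vector of sub-indices with logical attribute `overflow`.
#' @export
compute_iaqi <- function(conc, pollutant, table = aqi_breakpoints(),
                         round_up = TRUE) {
  if (any(is.na(conc))) stop("missing concentration")
  if (any(conc < 0)) stop("negative concentration")
  seg <- table[table$pollutant == pollutant, ]
  if (!nrow(seg)) stop("unknown pollutant: ", pollutant)
  seg <- seg[order(seg$bp_lo), ]
  top <- max(seg$iaqi_hi)
  cap <- max(seg$bp_hi)
  i <- findInterval(conc, seg$bp_lo, rightmost.closed = FALSE)
  i[i < 1] <- 1L
  i[i > nrow(seg)] <- nrow(seg)
  v <- (seg$iaqi_hi[i] - seg$iaqi_lo[i]) / (seg$bp_hi[i] - seg$bp_lo[i]) *
    (conc - seg$bp_lo[i]) + seg$iaqi_lo[i]
  over <- conc > cap
  v[over] <- top
  if (round_up) v <- ceiling(v)
  attr(v, "overflow") <- over
  v
}

.aqi_categories <- data.frame(
  category = c("excellent", "good", "mild", "moderate", "heavy", "severe"),
  upper = c(50, 100, 150, 200, 300, Inf)
)

#' Air-quality category for an AQI value
#'
#' @param aqi numeric AQI value(s).
#' @return factor with levels excellent/good/mild/moderate/heavy/severe
#'   (boundaries 50, 100, 150, 200, 300; each upper bound inclusive).
#' @export
aqi_category <- function(aqi) {
  idx <- findInterval(aqi, c(-Inf, .aqi_categories$upper), left.open = TRUE)
  factor(.aqi_categories$category[idx], levels = .aqi_categories$category)
}

#' Composite AQI from pollutant concentrations
#'
#' The composite index is the maximum of the per-pollutant sub-indices. The
#' pollutant(s) attaining that maximum are the primary pollutants; by
#' convention no primary pollutant is reported when AQI <= 50.
#'
#' @param conc named list/vector of concentrations for at least one pollutant.
#' @param table a [aqi_breakpoints()] table.
#' @return an `aqi_result` list: `iaqi` (named vector), `aqi`,
#'   `primary_pollutant` (character, possibly empty), `category`, `overflow`.
#' @export
compute_aqi <- function(conc, table = aqi_breakpoints()) {
  conc <- unlist(conc)
  conc <- conc[!is.na(conc)]
  if (!length(conc)) stop("no pollutant concentrations supplied")
  iaqi <- vapply(names(conc), function(p) {
    as.numeric(compute_iaqi(conc[[p]], p, table))
  }, numeric(1))
  over <- vapply(names(conc), function(p) {
    attr(compute_iaqi(conc[[p]], p, table), "overflow")
  }, logical(1))
  aqi <- max(iaqi)
  primary <- if (aqi > 50) names(iaqi)[iaqi == aqi] else character()
  structure(list(iaqi = iaqi, aqi = aqi, primary_pollutant = primary,
                 category = as.character(aqi_category(aqi)),
                 overflow = any(over)),
            class = "aqi_result")
}

#' Append sub-index, AQI and category columns to a daily series
#'
#' Computes `iaqi_<pollutant>` for every `conc_<pollutant>` column present,
#' plus `aqi` and `aqi_category`, leaving other columns untouched.
#'
#' @param series daily series (or any data frame with `conc_*` columns).
#' @param table a [aqi_breakpoints()] table.
#' @param overwrite recompute `aqi` even when the column already exists.
#' @return the series with appended columns.
#' @export
add_aqi <- function(series, table = aqi_breakpoints(), overwrite = FALSE) {
  if ("aqi" %in% names(series) && !overwrite) return(series)
  pols <- sub("^conc_", "", grep("^conc_", names(series), value = TRUE))
  pols <- intersect(pols, unique(table$pollutant))
  if (!length(pols)) stop("no pollutant concentration columns found")
  sub <- sapply(pols, function(p) {
    as.numeric(compute_iaqi(series[[paste0("conc_", p)]], p, table))
  })
  sub <- matrix(sub, nrow = nrow(series), dimnames = list(NULL, pols))
  for (p in pols) series[[paste0("iaqi_", p)]] <- sub[, p]
  series$aqi <- apply(sub, 1, max)
  series$aqi_category <- aqi_category(series$aqi)
  series
}
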