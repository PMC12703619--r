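#' Natural cubic spline specification
#'
#' Describes an `ns` term: either a target basis dimension `df` (interior
#' knots then fall at equally spaced quantiles of the data) or explicit
#' interior/boundary knots.
#'
#' @param df basis dimension (positive integer); ignored when `knots` given.
#' @param knots interior knot positions, strictly inside the boundary.
#' @param boundary two boundary knot positions; default is the data range.
#' @param include_intercept include the basis intercept column.
#' @return a `spline_spec` list.
#' @export
spline_spec <- function(df = NULL, knots = NULL, boundary = NULL,
                        include_intercept = FALSE) {
  if (is.null(df) && is.null(knots)) stop("need df or knots")
  if (!is.null(df) && (df < 1 || df != round(df))) {
    stop("df must be a positive integer")
  }
  if (!is.null(knots)) {
    if (is.unsorted(knots, strictly = TRUE)) {
      stop("knots must be strictly increasing (no duplicates)")
    }
  }
  if (!is.null(boundary)) {
    stopifnot(length(boundary) == 2, boundary[1] < boundary[2])
    if (!is.null(knots) &&
        (any(knots <= boundary[1]) || any(knots >= boundary[2]))) {
      stop("interior knots must lie strictly inside the boundary knots")
    }
  }
  structure(list(df = df, knots = knots, boundary = boundary,
                 include_intercept = include_intercept),
            class = "spline_spec")
}

#' Natural cubic spline basis
#'
#' Evaluates the natural cubic spline basis for `x`: piecewise-cubic columns
#' with continuous first and second derivatives at the knots and linear
#' behaviour beyond the boundary knots. Column count equals the spec's `df`.
#' Default interior knots sit at equally spaced quantiles of `x` and boundary
#' knots at the range of `x`; both are frozen into the returned attributes so
#' the same basis can be re-evaluated at new values (prediction).
#'
#' @param x numeric vector (finite).
#' @param spec a [spline_spec()]; an integer is promoted to `spline_spec(df=)`.
#' @return `length(x) x df` matrix with attributes `knots`, `boundary`,
#'   `include_intercept`.
#' @export
ns_basis <- function(x, spec) {
  if (is.numeric(spec) && length(spec) == 1) spec <- spline_spec(df = spec)
  stopifnot(inherits(spec, "spline_spec"))
  if (any(!is.finite(x))) stop("x must be finite")
  if (!is.null(spec$df) && spec$df >= length(unique(x)) && is.null(spec$knots)) {
    stop("df (", spec$df, ") must be smaller than the number of distinct x")
  }
  boundary <- spec$boundary
  if (is.null(boundary)) boundary <- range(x)
  if (!is.null(spec$knots)) {
    b <- splines::ns(x, knots = spec$knots, Boundary.knots = boundary,
                     intercept = spec$include_intercept)
  } else {
    # interior knot count for splines::ns: df - 1 - intercept
    n_int <- spec$df - 1L - as.integer(spec$include_intercept)
    if (n_int < 0) stop("df too small for include_intercept = TRUE")
    if (n_int > 0) {
      kn <- stats::quantile(x, probs = seq_len(n_int) / (n_int + 1),
                            names = FALSE, type = 7)
      if (any(duplicated(kn))) stop("duplicate quantile knots; reduce df")
      b <- splines::ns(x, knots = kn, Boundary.knots = boundary,
                       intercept = spec$include_intercept)
    } else {
      b <- splines::ns(x, df = spec$df, Boundary.knots = boundary,
                       intercept = spec$include_intercept)
    }
  }
  out <- matrix(as.numeric(b), nrow = length(x))
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  attr(out, "knots") <- as.numeric(attr(b, "knots"))
  attr(out, "boundary") <- as.numeric(attr(b, "Boundary.knots"))
  attr(out, "include_intercept") <- spec$include_intercept
  out
}

#' Re-evaluate a previously built natural spline basis at new values
#'
#' @param basis matrix returned by [ns_basis()].
#' @param x new values.
#' @return matrix with the same columns evaluated at `x`.
#' @export
ns_basis_predict <- function(basis, x) {
  b <- splines::ns(x, knots = attr(basis, "knots"),
                   Boundary.knots = attr(basis, "boundary"),
                   intercept = attr(basis, "include_intercept"))
  matrix(as.numeric(b), nrow = length(x),
         dimnames = list(NULL, colnames(basis)))
}

#' Smooth-trend spline for a daily calendar
#'
#' Convenience wrapper building the long-term-trend basis at a per-year
#' density: `df = df_per_year x n_years` (years counted as days / 365.25,
#' rounded up).
#'
#' @param dates `Date` vector.
#' @param df_per_year degrees of freedom per year (default 7).
#' @return an [ns_basis()] matrix over the day index.
#' @export
time_trend_basis <- function(dates, df_per_year = 7) {
  n_years <- max(1L, round(length(dates) / 365.25))
  ns_basis(as.numeric(dates), spline_spec(df = df_per_year * n_years))
}
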