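#' Cross-basis specification for a distributed-lag nonlinear model
#'
#' A cross-basis is the tensor product of a basis in the exposure dimension
#' and a basis in the lag dimension, summed over lags `0..max_lag`. With
#' `var_spec = "linear"` and `lag_spec = "indicator"` it reduces to an
#' ordinary distributed-lag model on the raw lagged exposures.
#'
#' @param var_spec exposure-dimension basis: `"linear"`, an integer df, or a
#'   [spline_spec()].
#' @param lag_spec lag-dimension basis: `"indicator"` (one column per lag), an
#'   integer df, or a [spline_spec()]. Spline lag bases include the intercept
#'   column so lag-constant effects stay representable.
#' @param max_lag maximum lag L (integer >= 0).
#' @param reference exposure value at which RR is pinned to 1; `NULL` defers
#'   to the series median at build time.
#' @return a `crossbasis_spec` list.
#' @export
crossbasis_spec <- function(var_spec = "linear", lag_spec = "indicator",
                            max_lag = 7, reference = NULL) {
  stopifnot(max_lag >= 0, max_lag == round(max_lag))
  norm <- function(s, lag = FALSE) {
    if (is.character(s)) {
      s <- match.arg(s, c("linear", "indicator"))
      if (!lag && s == "indicator") stop("'indicator' is a lag basis")
      if (lag && s == "linear") stop("'linear' is an exposure basis")
      return(s)
    }
    if (is.numeric(s) && length(s) == 1) {
      return(spline_spec(df = s, include_intercept = lag))
    }
    stopifnot(inherits(s, "spline_spec"))
    s
  }
  structure(list(var_spec = norm(var_spec), lag_spec = norm(lag_spec, TRUE),
                 max_lag = as.integer(max_lag), reference = reference),
            class = "crossbasis_spec")
}

# exposure basis evaluated at x, with construction metadata for re-evaluation
.var_basis <- function(x, spec, meta = NULL) {
  if (identical(spec, "linear")) {
    return(structure(matrix(x, ncol = 1, dimnames = list(NULL, "v1")),
                     meta = list(fun = "linear")))
  }
  if (is.null(meta)) {
    b <- ns_basis(x, spec)
    structure(b, meta = list(fun = "ns", knots = attr(b, "knots"),
                             boundary = attr(b, "boundary"),
                             include_intercept = attr(b, "include_intercept")))
  } else {
    b <- splines::ns(x, knots = meta$knots, Boundary.knots = meta$boundary,
                     intercept = meta$include_intercept)
    structure(matrix(as.numeric(b), nrow = length(x)), meta = meta)
  }
}

# lag basis: (max_lag + 1) x df_lag matrix over integer lags 0..L
.lag_basis <- function(lag_spec, max_lag) {
  lags <- 0:max_lag
  if (identical(lag_spec, "indicator")) {
    C <- diag(length(lags))
    colnames(C) <- paste0("l", lags)
    return(C)
  }
  if (max_lag == 0) {
    # degenerate window: lag dimension collapses to a constant
    return(matrix(1, 1, 1, dimnames = list(NULL, "l1")))
  }
  C <- ns_basis(lags, lag_spec)
  matrix(as.numeric(C), nrow = length(lags),
         dimnames = list(NULL, paste0("l", seq_len(ncol(C)))))
}

#' Build the cross-basis design matrix
#'
#' Row `t` of the design is
#' `vec( sum_l [f_var(x[t-l]) - f_var(x0)] (x) f_lag(l) )` for lags
#' `l = 0..max_lag`: the exposure basis is centered at the reference `x0`, so
#' a series held at the reference yields an all-zero design and fitted RRs are
#' pinned to 1 at `x0`. The first `max_lag` rows lack complete lagged history;
#' they carry `NA` and are flagged via the `incomplete` attribute so the
#' fitter drops them.
#'
#' @param x exposure series (numeric, length > `max_lag`).
#' @param spec a [crossbasis_spec()].
#' @return `n x (df_var * df_lag)` matrix of class `crossbasis` with
#'   attributes `spec`, `var_meta`, `lag_basis`, `reference`, `incomplete`,
#'   `df_var`, `df_lag`, `range`.
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(x)
  L <- spec$max_lag
  if (L >= n) stop("max_lag (", L, ") must be < series length (", n, ")")
  x0 <- spec$reference
  if (is.null(x0)) x0 <- stats::median(x)
  B <- .var_basis(x, spec$var_spec)
  meta <- attr(B, "meta")
  B0 <- .var_basis(x0, spec$var_spec, meta = meta)
  Bc <- sweep(unclass(B), 2, as.numeric(B0))
  C <- .lag_basis(spec$lag_spec, L)
  dvar <- ncol(Bc)
  dlag <- ncol(C)
  out <- matrix(NA_real_, n, dvar * dlag)
  for (i in seq_len(dvar)) {
    Li <- lag_matrix(Bc[, i], L)
    out[, (i - 1) * dlag + seq_len(dlag)] <- Li %*% C
  }
  colnames(out) <- paste0("cb.v", rep(seq_len(dvar), each = dlag),
                          ".", rep(colnames(C), dvar))
  structure(out,
            class = c("crossbasis", "matrix"),
            spec = spec, var_meta = meta, lag_basis = C,
            reference = x0, incomplete = seq_len(n) <= L,
            df_var = dvar, df_lag = dlag, range = range(x))
}

# contrast vectors for exposure x vs the reference, one row per lag 0..L
.cb_contrasts <- function(cb, x, allow_extrapolation = FALSE) {
  meta <- attr(cb, "var_meta")
  rng <- attr(cb, "range")
  if (!allow_extrapolation && (x < rng[1] || x > rng[2])) {
    stop("exposure ", x, " outside the basis range [", rng[1], ", ", rng[2],
         "]; set allow_extrapolation = TRUE to override")
  }
  spec <- attr(cb, "spec")
  fv <- as.numeric(.var_basis(x, spec$var_spec, meta = meta)) -
    as.numeric(.var_basis(attr(cb, "reference"), spec$var_spec, meta = meta))
  C <- attr(cb, "lag_basis")
  t(vapply(seq_len(nrow(C)), function(r) kronecker(fv, C[r, ]),
           numeric(length(fv) * ncol(C))))
}

#' Single-day and cumulative lag relative risks
#'
#' Converts the fitted cross-basis coefficient block into relative risks at
#' exposure `x` versus the cross-basis reference. In `single` mode, lag `l`
#' reports `exp(c_l . beta)` with `c_l = [f_var(x) - f_var(x0)] (x) f_lag(l)`;
#' in `cumulative` mode, lag `k` uses the contrast `sum_{l <= k} c_l`, so
#' cumulative log-RR at lag `k` is exactly the sum of the single-lag log-RRs
#' up to `k`. 95% intervals come from the quadratic form of the contrast
#' against the coefficient covariance.
#'
#' @param fit a [fit_poisson()] result whose design contained `cb`.
#' @param cb the [build_crossbasis()] matrix used in that design.
#' @param x exposure value at which to evaluate.
#' @param mode `"single"`, `"cumulative"`, or `"both"`.
#' @param block name of the coefficient block holding the cross-basis
#'   (default `"cb"`).
#' @param allow_extrapolation evaluate outside the exposure range seen at
#'   build time.
#' @return an `rr_table` data frame: `lag_kind`, `lag`, `logrr`, `se`, `rr`,
#'   `lower95`, `upper95`, `x`, `reference`.
#' @export
predict_rr <- function(fit, cb, x, mode = c("both", "single", "cumulative"),
                       block = "cb", allow_extrapolation = FALSE) {
  mode <- match.arg(mode)
  idx <- fit$block_index[[block]]
  if (is.null(idx)) stop("fit has no coefficient block named '", block, "'")
  beta <- fit$beta[idx]
  V <- fit$cov[idx, idx, drop = FALSE]
  Cm <- .cb_contrasts(cb, x, allow_extrapolation)
  if (length(beta) != ncol(Cm)) {
    stop("coefficient block length does not match the cross-basis width")
  }
  rows <- list()
  mk <- function(kind, lag, ctr) {
    lr <- as.numeric(ctr %*% beta)
    se <- sqrt(max(0, as.numeric(ctr %*% V %*% ctr)))
    data.frame(lag_kind = kind, lag = lag, logrr = lr, se = se,
               rr = exp(lr), lower95 = exp(lr - 1.96 * se),
               upper95 = exp(lr + 1.96 * se))
  }
  L <- nrow(Cm) - 1
  if (mode %in% c("both", "single")) {
    for (l in 0:L) rows[[length(rows) + 1]] <- mk("single", l, Cm[l + 1, ])
  }
  if (mode %in% c("both", "cumulative")) {
    acc <- rep(0, ncol(Cm))
    for (k in 0:L) {
      acc <- acc + Cm[k + 1, ]
      rows[[length(rows) + 1]] <- mk("cumulative", k, acc)
    }
  }
  out <- do.call(rbind, rows)
  out$x <- x
  out$reference <- attr(cb, "reference")
  class(out) <- c("rr_table", class(out))
  out
}
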