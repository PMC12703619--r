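test_that("a series held at the reference yields an all-zero design", {
  x <- rep(40, 50)
  cb <- build_crossbasis(x, crossbasis_spec(var_spec = "linear",
                                            lag_spec = "indicator",
                                            max_lag = 3, reference = 40))
  complete <- !attr(cb, "incomplete")
  expect_true(all(cb[complete, ] == 0))
})

test_that("linear x indicator reduces to raw lagged exposures", {
  set.seed(14)
  x <- runif(30, 20, 90)
  cb <- build_crossbasis(x, crossbasis_spec("linear", "indicator",
                                            max_lag = 2, reference = 50))
  m <- lag_matrix(x - 50, 2)
  keep <- !attr(cb, "incomplete")
  expect_equal(unclass(cb)[keep, ], unclass(m)[keep, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(is.na(unclass(cb)[!keep, ])))
})

test_that("cross-basis equals the explicit double-loop construction", {
  set.seed(15)
  x <- runif(120, 10, 150)
  spec <- crossbasis_spec(var_spec = 3, lag_spec = 3, max_lag = 4,
                          reference = 60)
  cb <- build_crossbasis(x, spec)
  # rebuild the centered marginal bases from the frozen knots
  meta <- attr(cb, "var_meta")
  B <- ns_basis(x, spline_spec(knots = meta$knots, boundary = meta$boundary))
  B0 <- ns_basis_predict(B, 60)
  Bc <- sweep(unclass(B), 2, as.numeric(B0))
  oracle <- oracle_crossbasis_loops(Bc, attr(cb, "lag_basis"), 4)
  keep <- !attr(cb, "incomplete")
  expect_lt(max(abs(unclass(cb)[keep, ] - oracle[keep, ])), 1e-10)
  expect_true(all(is.na(unclass(cb)[!keep, ])))
})

test_that("RR at the reference is exactly 1 with a degenerate interval", {
  s <- make_tiny_series(200)
  cb <- build_crossbasis(s$aqi, crossbasis_spec(3, 3, max_lag = 5))
  X <- cbind(1, unclass(cb))
  attr(X, "block_index") <- list(intercept = 1,
                                 cb = 1 + seq_len(ncol(cb)))
  fit <- fit_poisson(s$deaths_total, X)
  rr <- predict_rr(fit, cb, attr(cb, "reference"))
  expect_equal(rr$rr, rep(1, nrow(rr)))
  expect_equal(rr$lower95, rep(1, nrow(rr)))
  expect_equal(rr$upper95, rep(1, nrow(rr)))
})

test_that("cumulative log-RR is the running sum of single-lag log-RRs", {
  s <- make_tiny_series(300, seed = 16)
  cb <- build_crossbasis(s$aqi, crossbasis_spec(3, 3, max_lag = 7))
  X <- cbind(1, unclass(cb))
  attr(X, "block_index") <- list(intercept = 1, cb = 1 + seq_len(ncol(cb)))
  fit <- fit_poisson(s$deaths_total, X)
  rr <- predict_rr(fit, cb, 100)
  sing <- rr[rr$lag_kind == "single", ]
  cum <- rr[rr$lag_kind == "cumulative", ]
  for (k in 0:7) {
    expect_lt(abs(cum$logrr[cum$lag == k] -
                    sum(sing$logrr[sing$lag <= k])), 1e-10)
  }
  expect_equal(cum$logrr[cum$lag == 0], sing$logrr[sing$lag == 0])
})

test_that("linear x indicator coefficients match direct lagged regression", {
  set.seed(17)
  n <- 250
  x <- runif(n, 20, 90)
  y <- rpois(n, exp(2 + 0.002 * (x - 50)))
  cb <- build_crossbasis(x, crossbasis_spec("linear", "indicator",
                                            max_lag = 3, reference = 50))
  X <- cbind(1, unclass(cb))
  attr(X, "block_index") <- list(intercept = 1, cb = 2:5)
  fit <- fit_poisson(y, X)
  # direct distributed-lag Poisson regression on the lagged exposures
  lm4 <- lag_matrix(x - 50, 3)
  keep <- !attr(lm4, "incomplete")
  direct <- oracle_newton_poisson(y[keep], cbind(1, lm4[keep, ]))
  expect_lt(max(abs(fit$beta - direct$beta)), 1e-8)
  # per-lag RRs are the exponentiated per-lag coefficients (per unit exposure)
  rr <- predict_rr(fit, cb, 51, mode = "single")
  expect_equal(rr$logrr, unname(fit$beta[2:5]), tolerance = 1e-10)
})

test_that("exposures outside the basis range require explicit extrapolation", {
  s <- make_tiny_series(150, seed = 18)
  cb <- build_crossbasis(s$aqi, crossbasis_spec(3, 3, max_lag = 3))
  X <- cbind(1, unclass(cb))
  attr(X, "block_index") <- list(intercept = 1, cb = 1 + seq_len(ncol(cb)))
  fit <- fit_poisson(s$deaths_total, X)
  expect_error(predict_rr(fit, cb, max(s$aqi) + 50), "outside")
  expect_silent(predict_rr(fit, cb, max(s$aqi) + 50,
                           allow_extrapolation = TRUE))
})

test_that("degenerate windows and bad specs are handled", {
  x <- runif(20, 10, 50)
  cb0 <- build_crossbasis(x, crossbasis_spec("linear", 3, max_lag = 0,
                                             reference = 30))
  expect_equal(ncol(cb0), 1)  # lag dimension collapses
  expect_equal(unname(cb0[, 1]), x - 30, tolerance = 1e-12)
  expect_error(build_crossbasis(x, crossbasis_spec(max_lag = 20)),
               "max_lag")
  expect_error(crossbasis_spec(var_spec = "indicator"), "lag basis")
})
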