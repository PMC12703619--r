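make_phase1_series <- function(n = 700, seed = 30, ...) {
  simulate_daily_series(n_days = n, seed = seed, ...)
}

test_that("identical counts in two strata give identical results", {
  s <- make_phase1_series(500)
  s$deaths_female <- s$deaths_male
  s$deaths_ge65 <- s$deaths_male
  s$deaths_lt65 <- s$deaths_male
  s$deaths_total <- 2L * s$deaths_male
  res <- run_phase1(s, phase1_config(strata = c("male", "female")))
  expect_equal(res$male$rr_table, res$female$rr_table)
  expect_equal(res$male$fit$beta, res$female$fit$beta)
})

test_that("absent stratum columns are skipped with a warning", {
  s <- make_phase1_series(400)
  s$deaths_ge65 <- NULL
  expect_warning(res <- run_phase1(s, phase1_config(strata = c("total",
                                                               "ge65"))),
                 "ge65")
  expect_named(res, "total")
})

test_that("peak summaries attain the max RR with smallest-lag ties", {
  s <- make_phase1_series(600, seed = 31)
  res <- run_phase1(s, phase1_config(strata = "total"))
  rr <- res$total$rr_table
  sing <- rr[rr$lag_kind == "single", ]
  expect_equal(res$total$max_single_lag$rr, max(sing$rr))
  expect_equal(res$total$max_single_lag$lag,
               min(sing$lag[sing$rr == max(sing$rr)]))
})

test_that("the exposure-response curve is 1 at the reference and its
           turning point is the grid argmin", {
  s <- make_phase1_series(600, seed = 32)
  res <- run_phase1(s, phase1_config(strata = "total"))
  ref <- attr(res, "reference")
  crv <- exposure_response_curve(res$total$fit, res$total$cb,
                                 grid = c(ref - 10, ref, ref + 10))
  expect_equal(crv$rr[crv$x == ref], 1)
  full <- exposure_response_curve(res$total$fit, res$total$cb)
  expect_equal(attr(full, "turning_point"), full$x[which.min(full$rr)])
})

test_that("phase 1 is bit-reproducible for a fixed input and config", {
  s <- make_phase1_series(450, seed = 33)
  r1 <- run_phase1(s, phase1_config(strata = "total"))
  r2 <- run_phase1(s, phase1_config(strata = "total"))
  expect_identical(r1$total$rr_table, r2$total$rr_table)
})

test_that("a male-only exposure effect yields larger male peak cumulative RR", {
  wins <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    truth <- simulation_truth(slope = 0.003, threshold = 0,
                              lag_weights = c(0.4, 0.35, 0.25, 0, 0, 0, 0, 0),
                              stratum_effect_scale = c(male = 1, female = 0))
    s <- simulate_daily_series(n_days = 1200, seed = 100 + r, truth = truth)
    res <- run_phase1(s, phase1_config(var_df = "linear",
                                       strata = c("male", "female")))
    if (res$male$max_cumulative_lag$rr > res$female$max_cumulative_lag$rr) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 0.8 * reps)
})

test_that("with zero injected effect the per-lag CIs cover RR = 1", {
  reps <- 30
  covered <- 0
  total <- 0
  for (r in seq_len(reps)) {
    truth <- simulation_truth(slope = 0)
    s <- simulate_daily_series(n_days = 900, seed = 200 + r, truth = truth)
    res <- run_phase1(s, phase1_config(strata = "total"))
    sing <- res$total$rr_table
    sing <- sing[sing$lag_kind == "single", ]
    covered <- covered + sum(sing$lower95 <= 1 & sing$upper95 >= 1)
    total <- total + nrow(sing)
  }
  expect_gte(covered / total, 0.9)
})

test_that("a monotone simulated exposure-response is recovered", {
  truth <- simulation_truth(slope = 0.0025, threshold = 0,
                            lag_weights = c(0.4, 0.35, 0.25, 0, 0, 0, 0, 0))
  s <- simulate_daily_series(n_days = 2557, seed = 55, truth = truth)
  res <- run_phase1(s, phase1_config(strata = "total"))
  crv <- exposure_response_curve(res$total$fit, res$total$cb)
  truth_curve <- exp(0.0025 * (crv$x - attr(res, "reference")))
  expect_gt(cor(crv$rr, truth_curve, method = "spearman"), 0.9)
})

test_that("rr tables serialize in the published 16-row layout", {
  s <- make_phase1_series(400, seed = 34)
  res <- run_phase1(s, phase1_config(strata = "total"))
  tab <- format_rr_table(res$total$rr_table)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$lag_label[1:8], paste0("Lag", 0:7))
  expect_equal(tab$lag_label[9:16], paste0("Lag0", 0:7))
})
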