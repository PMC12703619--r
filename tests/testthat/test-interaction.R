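# a series whose day counts are exactly the chosen cell means, so the
# saturated 2x2 fit reproduces them without sampling noise
make_cell_series <- function(means, days_per_cell = 25) {
  cells <- expand.grid(E1 = 0:1, E2 = 0:1)
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(E1 = cells$E1[i], E2 = cells$E2[i],
               y = rep(means[i], days_per_cell))
  }))
  n <- nrow(rows)
  data.frame(date = as.Date("2015-01-01") + seq_len(n) - 1,
             deaths_total = as.integer(rows$y),
             aqi = ifelse(rows$E1 == 1, 120, 40),
             wind_mean = ifelse(rows$E2 == 1, 3, 1))
}

test_that("dichotomize tabulates cells exactly and refuses empty ones", {
  s <- make_tiny_series(200, seed = 40)
  inp <- dichotomize(s, "wind_mean", median(s$wind_mean), aqi_threshold = 60,
                     outcome = "deaths_total")
  # brute-force tabulation oracle
  e1 <- s$aqi > 60
  e2 <- s$wind_mean > median(s$wind_mean)
  expect_equal(inp$cells[1, 1], sum(!e1 & !e2))
  expect_equal(inp$cells[2, 2], sum(e1 & e2))
  expect_equal(sum(inp$cells), nrow(s))
  # E2 split at the median puts about half the days in each half
  expect_lt(abs(sum(inp$cells[, 2]) - nrow(s) / 2), nrow(s) * 0.1)
  expect_error(dichotomize(s, "wind_mean", median(s$wind_mean),
                           aqi_threshold = max(s$aqi) + 1),
               "cell \\(E1=1.*empty.*80")
})

test_that("sparse polluted cells trigger the threshold warning", {
  s <- make_tiny_series(200, seed = 41)
  s$aqi[1:10] <- 130  # just a handful of polluted days
  s$aqi[11:200] <- 50
  expect_warning(dichotomize(s, "wind_mean", median(s$wind_mean),
                             aqi_threshold = 100),
                 "polluted days")
})

test_that("no effect in any cell gives IRR 1, RERI 0, AP 0, verdict none", {
  s <- make_cell_series(c(5, 5, 5, 5))
  inp <- dichotomize(s, "wind_mean", 2, aqi_threshold = 100)
  res <- fit_interaction(inp)
  expect_equal(unname(res$IRR["est"]), 1, tolerance = 1e-9)
  expect_equal(unname(res$RERI["est"]), 0, tolerance = 1e-9)
  expect_equal(unname(res$AP["est"]), 0, tolerance = 1e-9)
  expect_equal(res$verdict, "none")
})

test_that("constructed cell means reproduce the arithmetic oracle exactly", {
  # baseline 10; RR10 = 1.2, RR01 = 1.3, RR11 = 2.0
  s <- make_cell_series(c(10, 12, 13, 20), days_per_cell = 40)
  inp <- dichotomize(s, "wind_mean", 2, aqi_threshold = 100)
  res <- fit_interaction(inp)
  expect_equal(unname(res$RR10["est"]), 1.2, tolerance = 1e-8)
  expect_equal(unname(res$RR01["est"]), 1.3, tolerance = 1e-8)
  expect_equal(unname(res$RR11["est"]), 2.0, tolerance = 1e-8)
  # direct arithmetic: RERI = 2 - 1.2 - 1.3 + 1, AP = RERI / RR11,
  # IRR = 2 / (1.2 * 1.3)
  expect_equal(unname(res$RERI["est"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(res$AP["est"]), 0.25, tolerance = 1e-8)
  expect_equal(unname(res$IRR["est"]), 2 / 1.56, tolerance = 1e-8)
  # saturated closed form: fitted cell means equal observed cell means
  mu <- res$fit$fitted
  expect_lt(max(abs(mu - s$deaths_total)), 1e-8)
})

test_that("interaction identities hold to numerical precision", {
  set.seed(42)
  s <- make_cell_series(c(8, 11, 9, 15), days_per_cell = 30)
  s$deaths_total <- rpois(nrow(s), s$deaths_total)
  if (all(s$deaths_total == 0)) s$deaths_total[1] <- 1
  inp <- dichotomize(s, "wind_mean", 2, aqi_threshold = 100)
  res <- fit_interaction(inp)
  rr10 <- unname(res$RR10["est"]); rr01 <- unname(res$RR01["est"])
  rr11 <- unname(res$RR11["est"])
  expect_lt(abs(unname(res$IRR["est"]) - rr11 / (rr01 * rr10)), 1e-12)
  expect_lt(abs(unname(res$RERI["est"]) - (rr11 - rr10 - rr01 + 1)), 1e-12)
  expect_lt(abs(unname(res$AP["est"]) * rr11 - unname(res$RERI["est"])),
            1e-12)
})

test_that("swapping the two exposures leaves IRR, RERI and AP unchanged", {
  set.seed(43)
  s <- make_cell_series(c(8, 11, 9, 15), days_per_cell = 30)
  s$deaths_total <- rpois(nrow(s), s$deaths_total)
  inp <- dichotomize(s, "wind_mean", 2, aqi_threshold = 100)
  swapped <- inp
  swapped$E1 <- inp$E2
  swapped$E2 <- inp$E1
  a <- fit_interaction(inp)
  b <- fit_interaction(swapped)
  expect_equal(a$IRR["est"], b$IRR["est"], tolerance = 1e-10)
  expect_equal(a$RERI["est"], b$RERI["est"], tolerance = 1e-10)
  expect_equal(a$AP["est"], b$AP["est"], tolerance = 1e-10)
})

test_that("verdicts follow the RERI interval sign rules", {
  set.seed(44)
  big <- make_cell_series(c(50, 55, 60, 160), days_per_cell = 120)
  big$deaths_total <- rpois(nrow(big), big$deaths_total)
  syn <- fit_interaction(dichotomize(big, "wind_mean", 2,
                                     aqi_threshold = 100))
  expect_equal(syn$verdict, "synergistic")
  expect_gt(syn$RERI[2], 0)
  ant <- make_cell_series(c(50, 100, 100, 110), days_per_cell = 120)
  ant$deaths_total <- rpois(nrow(ant), ant$deaths_total)
  res_ant <- fit_interaction(dichotomize(ant, "wind_mean", 2,
                                         aqi_threshold = 100))
  expect_equal(res_ant$verdict, "antagonistic")
  expect_lt(res_ant$RERI[3], 0)
})

test_that("the adjusted sensitivity fit runs and keeps the same structure", {
  truth <- simulation_truth(interaction_gamma = log(0.9),
                            interaction_aqi_threshold = 45)
  s <- simulate_daily_series(800, seed = 45, truth = truth)
  inp <- dichotomize(s, "wind_mean", median(s$wind_mean), aqi_threshold = 45)
  res <- fit_interaction(inp, adjusted = TRUE, series = s)
  expect_true(res$verdict %in% c("synergistic", "antagonistic", "none"))
  expect_true(all(c("time", "dow") %in% names(res$fit$block_index)))
})

test_that("run_phase2 returns one row per meteorological variable", {
  s <- simulate_daily_series(900, seed = 46)
  tab <- run_phase2(s, c(wind_mean = median(s$wind_mean),
                         humidity_mean = median(s$humidity_mean)),
                    aqi_threshold = 60)
  expect_equal(tab$variable, c("wind_mean", "humidity_mean"))
  expect_equal(tab$n00 + tab$n01 + tab$n10 + tab$n11, rep(nrow(s), 2))
})
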