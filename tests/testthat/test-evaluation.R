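# Budgets, NUE, reductions, quality map, ratio stats, correlation.

test_that("n_budget matches direct arithmetic", {
  # two-year totals: clipping 184.2, control 64.9, N 80 -> 58.2%
  b <- n_budget(184.2, 80, 64.9)
  expect_equal(b$uptake, 184.2 * 0.39, tolerance = 1e-12)
  expect_equal(b$nue, (184.2 - 64.9) * 0.39 / 80 * 100, tolerance = 1e-12)
  expect_equal(round(b$nue, 1), 58.2)
  expect_equal(n_budget(200, 100, 50)$nue, 58.5, tolerance = 1e-12)
  # fertilized clipping equal to control: nothing attributable -> 0%
  expect_equal(n_budget(64.9, 80, 64.9)$nue, 0)
  # unfertilized control: NUE undefined
  expect_true(is.na(n_budget(64.9, 0, 64.9)$nue))
})

test_that("NUE scales linearly as the formula dictates", {
  b1 <- n_budget(200, 100, 50)
  b2 <- n_budget(400, 100, 100)   # clipping doubled, same N
  expect_equal(b2$nue, 2 * b1$nue, tolerance = 1e-12)
  b3 <- n_budget(200, 200, 50)    # N doubled
  expect_equal(b3$nue, b1$nue / 2, tolerance = 1e-12)
})

test_that("percent reductions reproduce the printed integers", {
  expect_equal(percent_reduction(281, 190), 32)
  expect_equal(percent_reduction(281, 136), 52)
  expect_equal(percent_reduction(281, 80), 72)
  expect_equal(percent_reduction(100, 100), 0)
  # complement identity before rounding
  p <- percent_reduction(281, 190, digits = NULL)
  expect_equal(p + 190 / 281 * 100, 100, tolerance = 1e-12)
  expect_error(percent_reduction(0, 10), "positive")
})

test_that("quality map interpolates the anchors and clips to [1, 9]", {
  expect_equal(quality_from_clipping(1.25), 6)
  expect_equal(quality_from_clipping(1.6), 7)
  expect_equal(quality_from_clipping(1.425), 6.5)
  expect_equal(quality_from_clipping(0), 1)     # floored
  expect_equal(quality_from_clipping(10), 9)    # ceiling
  y <- seq(0, 4, by = 0.01)
  q <- quality_from_clipping(y)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= 1 & q <= 9))
})

test_that("ratio stats summarize predicted/observed correctly", {
  obs <- c(10, 12, 15, 20)
  r1 <- ratio_stats(obs, obs)
  expect_equal(unlist(r1[c("min", "q25", "median", "q75", "max")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_equal(ratio_stats(2 * obs, obs)$median, 2)
  rs <- ratio_stats(c(8, 30, 15, 22), obs)
  expect_true(rs$min <= rs$q25 && rs$q25 <= rs$median &&
                rs$median <= rs$q75 && rs$q75 <= rs$max)
  expect_error(ratio_stats(1:3, 1:4), "length")
  expect_error(ratio_stats(1:3, c(1, 0, 2)), "positive")
})

test_that("GP overpredicts growth when the green can only grow half the cap", {
  # simulator limited to half the dosing model's maximum growth rate: the
  # GP-as-predictor ratio must sit above 1 (qualitative overprediction)
  g_half <- growth_params(gmax = 1.6)
  run <- run_season(zone_a(), climate_config(seed = 3), strategy_gp(),
                    seed = 3, growth = g_half)
  log <- run$fert_log
  pred <- log$input_value * 3.2 * 14     # implied biweekly growth forecast
  obs_daily <- run$observations$clipping_yield
  observed <- vapply(seq_len(nrow(log)), function(k) {
    i <- match(log$date[k], run$observations$date)
    sum(obs_daily[i:min(length(obs_daily), i + 13)])
  }, 0)
  expect_gt(ratio_stats(pred, observed)$median, 1)
})

test_that("pearson correlation matches the closed-form oracle", {
  expect_equal(ndre_clipping_correlation(1:10, 2 * (1:10))$r, 1)
  expect_equal(ndre_clipping_correlation(1:10, -(1:10))$r, -1)
  xy <- with_seed(8, list(x = runif(20), y = runif(20)))
  hand <- sum((xy$x - mean(xy$x)) * (xy$y - mean(xy$y))) /
    sqrt(sum((xy$x - mean(xy$x))^2) * sum((xy$y - mean(xy$y))^2))
  expect_equal(ndre_clipping_correlation(xy$x, xy$y)$r, hand, tolerance = 1e-12)
  expect_true(is.na(ndre_clipping_correlation(rep(1, 5), 1:5)$r))
  expect_error(ndre_clipping_correlation(1:2, 1:2), "3 complete pairs")
})
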