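# Experience schedule and NDRE threshold rule.

test_that("experience schedule totals dose x floor(weeks/2) per season", {
  s <- strategy_experience()  # 10 kg ha-1 biweekly, 30 weeks
  days <- seq(s$season_start, by = 1, length.out = s$season_weeks * 7)
  recs <- lapply(days, experience_dose, schedule = s)
  total <- sum(vapply(recs, `[[`, 0, "dose_kg_ha"))
  expect_equal(total, 150)                       # ~150 kg ha-1 per season
  expect_equal(total, s$dose * floor(s$season_weeks / 2))
  # a 4-week season has exactly 2 events
  s4 <- strategy_experience(season_weeks = 4)
  days4 <- seq(s4$season_start, by = 1, length.out = 28)
  doses4 <- vapply(days4, function(d) experience_dose(d, s4)$dose_kg_ha, 0)
  expect_equal(sum(doses4 > 0), 2)
  expect_equal(sum(doses4), 20)
})

test_that("zero-dose schedule is all zero and off-season dates are flagged", {
  s0 <- strategy_experience(dose = 0)
  expect_equal(experience_dose("2021-06-12", s0)$dose_kg_ha, 0)
  off <- experience_dose("2021-03-01", strategy_experience())
  expect_equal(off$dose_kg_ha, 0)
  expect_equal(off$branch, "off-season")
})

test_that("ndre rule withholds only above the 0.28 reference", {
  hist <- function(v) data.frame(date = as.Date("2021-06-01") + 0:13, ndre = v)
  d <- as.Date("2021-06-14")
  expect_equal(ndre_dose(hist(rep(0.30, 14)), d)$dose_kg_ha, 0)
  expect_equal(ndre_dose(hist(rep(0.30, 14)), d)$branch, "sufficient")
  expect_equal(ndre_dose(hist(rep(0.25, 14)), d)$dose_kg_ha, 10)
  # boundary: mean exactly 0.28 still fertilizes (withhold needs strictly >)
  expect_equal(ndre_dose(hist(rep(0.28, 14)), d)$dose_kg_ha, 10)
  expect_error(ndre_dose(hist(rep(0.3, 14)), as.Date("2021-09-01")), "window")
  expect_error(ndre_dose(NULL, d), "reading")
})

test_that("ndre dose is a non-increasing step function of the window mean", {
  d <- as.Date("2021-06-14")
  means <- seq(0.2, 0.4, by = 0.005)
  doses <- vapply(means, function(m) {
    h <- data.frame(date = d - 0:4, ndre = rep(m, 5))
    ndre_dose(h, d)$dose_kg_ha
  }, 0)
  expect_true(all(diff(doses) <= 0))
  expect_setequal(unique(doses), c(10, 0))
})

test_that("the lookback window is half-open: (d - 14, d]", {
  d <- as.Date("2021-06-15")
  h <- data.frame(date = c(d - 14, d - 13, d), ndre = c(0.9, 0.1, 0.1))
  # the d - 14 reading falls outside; mean is 0.1 -> fertilize
  expect_equal(ndre_dose(h, d)$info$mean_ndre, 0.1)
})

test_that("over a season the NDRE rule never applies more N than the schedule", {
  for (s in 1:5) {
    w <- generate_weather(climate_config(seed = s))
    r_nd <- run_season(zone_a(), strategy = strategy_ndre(), seed = s, weather = w)
    r_ex <- run_season(zone_a(), strategy = strategy_experience(), seed = s, weather = w)
    expect_lte(season_n_applied(r_nd), season_n_applied(r_ex))
  }
})
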