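# Feature assembly, growth-model training and clipping-replacement dosing.

const_obs <- function(n = 30, clip = 2, ndre = 0.3, moist = 20, traffic = 30) {
  data.frame(date = as.Date("2021-05-01") + seq_len(n) - 1,
             clipping_yield = clip, ndre = ndre, soil_moisture = moist,
             traffic = traffic, quality = 7)
}

const_weather <- function(n = 30) {
  w <- generate_weather(climate_const20(max(n, 28)))
  w[seq_len(n), ]
}

test_that("feature rows are one per collection event with correct lags", {
  obs <- const_obs(30)
  obs$soil_moisture <- rep(c(20, 30), 15)   # alternating readings
  ts <- build_features(obs, const_weather(30), NULL, "A", sampling_interval = 2)
  expect_equal(nrow(ts$features), 15)
  expect_true(all(ts$features$days_between_mowing == 2))
  # first event averages the day-2 reading with the first available one;
  # later events average the event reading with the previous event's (both 30)
  expect_equal(ts$features$soil_moisture_3d[1], mean(c(20, 30)))
  expect_equal(ts$features$soil_moisture_3d[2], 30)
  # per-event target = sum of daily clipping since the previous collection
  expect_equal(ts$targets, rep(4, 15))
})

test_that("soil moisture 20 then 30 averages to 25 on the second event", {
  obs <- const_obs(4)
  obs$soil_moisture <- c(15, 20, 25, 30)    # event days are 2 and 4
  ts <- build_features(obs, const_weather(4), NULL, "A")
  expect_equal(ts$features$soil_moisture_3d[2], 25)
})

test_that("events without weather are dropped with a message", {
  obs <- const_obs(30)
  w <- const_weather(30)[-c(10, 12), ]      # remove two event days
  expect_message(ts <- build_features(obs, w, NULL, "A"), "dropped")
  expect_equal(nrow(ts$features), 13)
  expect_error(build_features(const_obs(10), const_weather(10)[0, ], NULL, "A"),
               "overlapping")
})

test_that("recent N rate feature sums doses in the trailing 14 days", {
  obs <- const_obs(30)
  fert <- data.frame(date = as.Date("2021-05-01") + c(0, 14),
                     dose_kg_ha = c(10, 8))
  ts <- build_features(obs, const_weather(30), fert, "A")
  # event on day 2 sees only the day-1 application
  expect_equal(ts$features$n_rate_recent[1], 10)
  # event on day 16 (2021-05-16) sees day-15's 8 plus day-1 outside window
  expect_equal(ts$features$n_rate_recent[8], 8)
})

test_that("constant-target training predicts the constant", {
  ts <- build_features(const_obs(120), const_weather(120), NULL, "A")
  m <- train_growth_model(ts, seed = 1, n_trees = 20)
  expect_equal(unname(predict(m, ts$features)), rep(4, nrow(ts$features)),
               tolerance = 1e-6)
})

test_that("degenerate features fall back to a mean predictor with a warning", {
  ts <- build_features(const_obs(120), const_weather(120), NULL, "A")
  ts$features[] <- lapply(ts$features, function(c) rep(c[1], length(c)))
  expect_warning(m <- train_growth_model(ts, seed = 1), "degenerate")
  expect_equal(predict_biweekly_yield(m, ts$features[1:7, ]), 7 * 4)
})

test_that("training floor on rows is enforced", {
  ts <- build_features(const_obs(30), const_weather(30), NULL, "A")
  expect_error(train_growth_model(ts, min_rows = 50), ">= 50")
})

test_that("biweekly prediction sums per-event predictions", {
  m <- structure(list(forest = NULL, mean = 2.86), class = "growth_predictor")
  feats <- const_obs(7)   # any 7 rows; mean predictor ignores them
  expect_equal(predict_biweekly_yield(m, feats), 7 * 2.86)
  expect_error(predict_biweekly_yield(m, feats[0, ]), "empty")
})

test_that("forest predictions ignore row order", {
  ts <- with_seed(3, {
    obs <- const_obs(120)
    obs$clipping_yield <- runif(120, 1, 3)
    obs$ndre <- runif(120, 0.25, 0.35)
    build_features(obs, generate_weather(climate_config(seed = 2))[1:120, ], NULL, "A")
  })
  m <- train_growth_model(ts, seed = 2, n_trees = 50)
  perm <- with_seed(5, sample(nrow(ts$features)))
  expect_equal(predict(m, ts$features[perm, ]),
               predict(m, ts$features)[perm], tolerance = 1e-12)
})

test_that("the three-branch replacement rule matches its arithmetic", {
  expect_equal(mlrf_dose(20)$dose_kg_ha, 7.8)        # in-band replacement
  expect_equal(mlrf_dose(20)$branch, "replacement")
  expect_equal(mlrf_dose(10)$dose_kg_ha, 7.8)        # below band: median 20
  expect_equal(mlrf_dose(10)$branch, "below-band")
  expect_equal(mlrf_dose(25)$dose_kg_ha, 0)
  expect_equal(mlrf_dose(25)$branch, "above-band")
  expect_equal(mlrf_dose(17.5)$dose_kg_ha, 6.825)    # boundary inclusive
  expect_equal(mlrf_dose(17.5)$branch, "replacement")
  expect_equal(mlrf_dose(22.5)$dose_kg_ha, 8.775)
  expect_error(mlrf_dose(-1), "non-negative")
})

test_that("the dose function is piecewise and bounded by 8.775", {
  y <- seq(0, 40, by = 0.25)
  d <- vapply(y, function(v) mlrf_dose(v)$dose_kg_ha, 0)
  expect_true(all(d <= 22.5 * 0.039 * 10 + 1e-12))
  expect_equal(d[y < 17.5], rep(20 * 0.039 * 10, sum(y < 17.5)),
               tolerance = 1e-12)                    # constant below band
  in_band <- y >= 17.5 & y <= 22.5
  expect_equal(d[in_band], y[in_band] * 0.039 * 10, tolerance = 1e-12)
  expect_true(all(d[y > 22.5] == 0))                 # zero above band
})

test_that("a forest trained on a prior season tracks a held-out season", {
  zA <- zone_a()
  w1 <- generate_weather(climate_config(seed = 11))
  w2 <- generate_weather(climate_config(seed = 22))
  run1 <- run_season(zA, strategy = strategy_experience(), seed = 5, weather = w1)
  ts1 <- build_features(run1$observations, run1$weather, run1$fert_log, zA)
  m <- train_growth_model(ts1, seed = 9, n_trees = 200)
  run2 <- run_season(zA, strategy = strategy_experience(), seed = 6, weather = w2)
  ts2 <- build_features(run2$observations, run2$weather, run2$fert_log, zA)
  pred <- predict(m, ts2$features)
  r <- biweekly_sums(pred, ts2$dates) / biweekly_sums(ts2$targets, ts2$dates)
  expect_gte(mean(r >= 0.8 & r <= 1.2), 0.8)
})
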