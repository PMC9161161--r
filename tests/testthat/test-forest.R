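# The regression forest itself (the engine under the growth model).

make_xy <- function(n, seed) {
  with_seed(seed, {
    x <- data.frame(a = runif(n, 0, 10), b = runif(n, -1, 1),
                    g = sample(c("u", "v"), n, TRUE))
    y <- 2 * x$a + 3 * (x$g == "v") + rnorm(n, 0, 0.3)
    list(x = x, y = y)
  })
}

test_that("constant targets give constant predictions", {
  d <- make_xy(60, 1)
  f <- regression_forest(d$x, rep(4.2, 60), n_trees = 50, seed = 2)
  expect_equal(predict(f, d$x), rep(4.2, 60), tolerance = 1e-6)
})

test_that("fits are reproducible under a fixed seed", {
  d <- make_xy(80, 2)
  f1 <- regression_forest(d$x, d$y, n_trees = 30, seed = 7)
  f2 <- regression_forest(d$x, d$y, n_trees = 30, seed = 7)
  expect_identical(predict(f1, d$x), predict(f2, d$x))
  f3 <- regression_forest(d$x, d$y, n_trees = 30, seed = 8)
  expect_false(identical(predict(f1, d$x), predict(f3, d$x)))
})

test_that("predictions are invariant to row order", {
  d <- make_xy(50, 3)
  f <- regression_forest(d$x, d$y, n_trees = 40, seed = 1)
  perm <- with_seed(4, sample(50))
  expect_equal(predict(f, d$x[perm, ]), predict(f, d$x)[perm], tolerance = 1e-12)
})

test_that("the forest learns a signal a permuted fit cannot", {
  d <- make_xy(120, 5)
  train <- 1:80; test <- 81:120
  f <- regression_forest(d$x[train, ], d$y[train], n_trees = 100, seed = 1)
  y_shuf <- with_seed(6, sample(d$y[train]))
  f_shuf <- regression_forest(d$x[train, ], y_shuf, n_trees = 100, seed = 1)
  err <- mean((predict(f, d$x[test, ]) - d$y[test])^2)
  err_shuf <- mean((predict(f_shuf, d$x[test, ]) - d$y[test])^2)
  expect_lt(err, err_shuf)
})

test_that("unseen factor levels and mismatched columns are rejected", {
  d <- make_xy(40, 7)
  f <- regression_forest(d$x, d$y, n_trees = 10, seed = 1)
  bad <- d$x; bad$g[1] <- "w"
  expect_error(predict(f, bad), "unseen level")
  expect_error(predict(f, d$x[, 1:2]), "feature")
})
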