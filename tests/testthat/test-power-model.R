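# Small regression problems for forest tests: smooth target of a few
# feature columns, so fits are learnable at tiny n.
make_forest_data <- function(n, p = 6, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- 2 * x[, 1] - x[, 2]^2 + noise * rnorm(n)
    list(x = x, y = y)
  })
}

test_that("the pooled weighted quantile reproduces the elementary examples", {
  # one tree, leaf responses [1,2,3,4]
  expect_equal(pooled_quantile(list(c(1, 2, 3, 4)), c(0, 0.5, 1)),
               c(1, 2.5, 4))
  # two trees with point-mass leaves [0,0] and [10,10]
  expect_equal(pooled_quantile(list(c(0, 0), c(10, 10)), 0.5), 5)
  # unequal leaf sizes: each response weighted 1/(n_trees * leaf size)
  leaves <- list(c(0, 10), c(5, 5, 5, 5, 5))
  expect_equal(pooled_quantile(leaves, 0.5),
               oracle_weighted_quantile(c(0, 10, rep(5, 5)),
                                        c(1/4, 1/4, rep(1/10, 5)), 0.5))
})

test_that("weighted quantiles reduce to type-7 quantiles under equal weights", {
  set.seed(8)
  for (rep in 1:20) {
    v <- rnorm(sample(3:40, 1))
    q <- runif(5)
    expect_equal(weighted_quantile(v, rep(1, length(v)), q),
                 unname(quantile(v, q, type = 7)))
  }
})

test_that("forest training is deterministic and respects leaf-size bounds", {
  d <- make_forest_data(150, noise = 0.1)
  m1 <- train_forest(d$x, d$y, n_trees = 10, min_leaf = 5, seed = 42)
  m2 <- train_forest(d$x, d$y, n_trees = 10, min_leaf = 5, seed = 42)
  probe <- make_forest_data(20, seed = 9)$x
  expect_identical(predict_quantile(m1, probe, 0.5),
                   predict_quantile(m2, probe, 0.5))
  m3 <- train_forest(d$x, d$y, n_trees = 10, min_leaf = 5, seed = 43)
  expect_false(identical(predict_quantile(m1, probe, 0.5),
                         predict_quantile(m3, probe, 0.5)))
  # every leaf retains at least min_leaf responses
  expect_true(all(unlist(lapply(m1$leaf_values, lengths)) >= 5))
  expect_error(train_forest(d$x[1:3, ], d$y[1:3], min_leaf = 5), "at least 5")
})

test_that("degenerate targets give degenerate predictions", {
  d <- make_forest_data(120)
  m <- train_forest(d$x, rep(0, 120), n_trees = 5, seed = 1)
  probe <- make_forest_data(10, seed = 3)$x
  for (q in c(0, 0.3, 0.5, 1)) {
    expect_equal(predict_quantile(m, probe, q), rep(0, 10))
  }
})

test_that("a deep single tree recovers a target equal to one feature column", {
  d <- make_forest_data(200, noise = 0, seed = 5)
  y <- d$x[, 1]
  m <- train_forest(d$x, y, n_trees = 1, min_leaf = 1, mtry = ncol(d$x),
                    seed = 7)
  pred <- predict_quantile(m, d$x, 0.5)
  expect_gte(cor(pred, y), 0.99)
  # in-bag rows sit in their own leaves and are reproduced exactly
  inbag <- m$forest$inbag.counts[[1]] > 0
  expect_equal(pred[inbag], y[inbag], tolerance = 1e-12)
})

test_that("predict_quantile equals the enumerated oracle on small forests", {
  qs <- seq(0, 1, by = 0.1)
  for (cfg in list(list(n = 30, trees = 1), list(n = 50, trees = 3))) {
    d <- make_forest_data(cfg$n, noise = 0.3, seed = cfg$n)
    m <- train_forest(d$x, d$y, n_trees = cfg$trees, min_leaf = 5,
                      seed = 11)
    probe <- make_forest_data(8, seed = cfg$n + 1)$x
    want <- oracle_forest_quantile(m, d$x, d$y, probe, qs)
    for (j in seq_along(qs)) {
      expect_equal(predict_quantile(m, probe, qs[j]), want[, j],
                   tolerance = 1e-12)
    }
  }
})

test_that("predicted quantiles are monotone in q", {
  d <- make_forest_data(200, noise = 0.5, seed = 21)
  m <- train_forest(d$x, d$y, n_trees = 10, seed = 2)
  probe <- make_forest_data(100, seed = 22)$x
  q_lo <- runif(100)
  q_hi <- pmin(1, q_lo + runif(100))
  lo <- predict_quantile(m, probe, q_lo)
  hi <- predict_quantile(m, probe, q_hi)
  expect_true(all(hi >= lo))
})

test_that("prediction rejects a mismatched feature schema", {
  d <- make_forest_data(120)
  m <- train_forest(d$x, d$y, n_trees = 3, seed = 1)
  bad <- d$x
  colnames(bad)[2] <- "wrong"
  expect_error(predict_quantile(m, bad, 0.5), "schema")
})

test_that("calibration records segment extrema and rejects degenerate segments", {
  cal <- fit_calibration(c(-0.5, 0.2, 1.9))
  expect_equal(cal$cal_min, -0.5)
  expect_equal(cal$cal_max, 1.9)
  expect_error(fit_calibration(c(1, 1)), "constant")
  expect_error(fit_calibration(3), "at least 2")
  # values inside the extrema leave the calibration unchanged
  cal2 <- fit_calibration(c(-0.5, 0.2, 1.9, 0, 1, 1.5))
  expect_equal(cal2, cal)
})

test_that("the calibration maps raw predictions to quantile probabilities", {
  cal <- fit_calibration(c(0, 2))
  expect_equal(calibration_probability(1.5, cal), 0.75)
  expect_equal(calibration_probability(0, cal), 0)
  expect_equal(calibration_probability(c(-3, 5), cal), c(0, 1))  # clipped
})

test_that("calibrated prediction selects the calibration-probability quantile", {
  d <- make_forest_data(150, noise = 0.3, seed = 31)
  m <- train_forest(d$x, d$y, n_trees = 5, seed = 3)
  probe <- make_forest_data(25, seed = 32)$x
  raw <- predict_quantile(m, probe, 0.5)
  cal <- fit_calibration(raw)
  got <- predict_calibrated(m, probe, cal)
  qn <- calibration_probability(raw, cal)
  expect_equal(got, predict_quantile(m, probe, qn))
})

test_that("single-response leaves make calibration a no-op", {
  d <- make_forest_data(100, noise = 0.2, seed = 41)
  m <- train_forest(d$x, d$y, n_trees = 1, min_leaf = 1, seed = 4)
  probe <- make_forest_data(30, seed = 42)$x
  raw <- predict_quantile(m, probe, 0.5)
  # leaves are near point masses; all quantiles of a point mass coincide
  cal <- fit_calibration(raw)
  expect_equal(predict_calibrated(m, probe, cal), raw)
})
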