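test_that("regression metrics match closed forms on hand-computable series", {
  y <- c(0, 1, 5)
  m <- regression_metrics(y, y)
  expect_equal(m$R, 1)
  expect_equal(m$RMSE, 0)
  expect_equal(m$NRMSE, 0)

  shifted <- regression_metrics(y, y + 0.5)
  expect_equal(shifted$R, 1)
  expect_equal(shifted$RMSE, 0.5)
  expect_equal(shifted$NRMSE, 100 * 0.5 / 5)

  # RMSE 0.05 against a reference spanning 5 w/kg is 1% NRMSE
  y2 <- c(0, 2.5, 5)
  m2 <- regression_metrics(y2, y2 + 0.05)
  expect_equal(m2$NRMSE, 1)

  expect_error(regression_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(regression_metrics(1:3, 1:4), "lengths")

  # alternative NRMSE denominators
  expect_equal(regression_metrics(y2, y2 + 0.05, "mean")$NRMSE, 100 * 0.05 / 2.5)
  expect_equal(regression_metrics(y2, y2 + 0.05, "max")$NRMSE, 1)
})

test_that("per-cycle peaks and occurrences follow the argmax rule", {
  power <- rep(0, 250)
  power[59] <- 2          # offset 58 within the cycle starting at sample 1
  power[160] <- 3
  cycles <- data.frame(start = c(1, 101), end = c(101, 221))
  pk <- peak_analysis(power, cycles)
  expect_equal(pk$peak, c(2, 3))
  expect_equal(pk$occurrence[1], 58)
  expect_equal(pk$occurrence[2], 100 * 59 / 120)
  expect_false(any(pk$degenerate))

  # first-index tie-break and the degenerate flag
  flat <- peak_analysis(rep(1, 100), data.frame(start = 1, end = 51))
  expect_equal(flat$occurrence, 0)
  expect_true(flat$degenerate)

  # occurrence is invariant to adding a constant within a cycle
  pk2 <- peak_analysis(power + 7, cycles)
  expect_equal(pk2$occurrence, pk$occurrence)
  expect_equal(pk2$peak, pk$peak + 7)

  empty <- peak_analysis(power, data.frame(start = integer(0), end = integer(0)))
  expect_equal(nrow(empty), 0)
})

test_that("relative peak error is the range-normalised peak difference", {
  expect_equal(relative_peak_error(1.8, 1.7, 2.0), 5)
  expect_equal(relative_peak_error(1.7, 1.7, 2.0), 0)
  expect_equal(relative_peak_error(1.69, 1.70, 2.452), -0.41, tolerance = 0.01)
  expect_error(relative_peak_error(1, 1, 0), "positive")
})

test_that("the intra-subject protocol learns a noiseless subject almost perfectly", {
  coh <- make_test_cohort(n_subjects = 1, speeds = c(0.4, 0.7, 1.0, 1.3, 1.6),
                          duration = 20, noise_sd = 0, seed = 51)
  rep <- run_intra_subject(coh, power_config(seed = 5))
  expect_s3_class(rep, "eval_report")
  expect_gte(rep$aggregate$R, 0.99)
  expect_equal(nrow(rep$per_speed), 5)
  expect_equal(nrow(rep$cells), 5)
  expect_true(all(rep$cells$R >= -1 & rep$cells$R <= 1))
  expect_true(all(rep$cells$RMSE >= 0))
  expect_true(all(rep$cells$true_occurrence >= 0 &
                    rep$cells$true_occurrence <= 100))
})

test_that("calibration boosts peaks and deepens valleys on synthetic test trials", {
  coh <- make_test_cohort(n_subjects = 1, speeds = c(0.7, 1.3),
                          duration = 15, noise_sd = 0.1, seed = 52)
  config <- power_config(seed = 6)
  n <- nrow(coh[[1]]$data)
  halves <- lapply(coh, trial_slice, from = 1, to = n %/% 2)
  model <- train_power_model(halves, config)
  for (tr in coh) {
    fit <- predict_power(model, trial_slice(tr, n %/% 2 + 1, n))
    cal <- fit_calibration(fit$power[seq_len(nrow(fit) %/% 2)])
    calibrated <- predict_power(model, trial_slice(tr, n %/% 2 + 1, n), cal)
    expect_gte(max(calibrated$power), max(fit$power))
    expect_lte(min(calibrated$power), min(fit$power))
  }
})

test_that("leave-one-subject-out generalises across noiseless subjects", {
  coh <- make_test_cohort(n_subjects = 3, speeds = c(0.4, 0.7, 1.0, 1.3, 1.6),
                          duration = 30, noise_sd = 0, seed = 53)
  config <- power_config(seed = 7, train_stride = 3)
  rep <- run_inter_subject(coh, config)
  expect_gte(rep$aggregate$R, 0.95)
  # every subject appears exactly once as a test subject
  expect_equal(sort(unique(rep$cells$subject)), c("S1", "S2", "S3"))
  expect_equal(unname(table(rep$cells$subject)), rep(5L, 3), ignore_attr = TRUE)
})

test_that("protocols never leak the test subject into training", {
  coh <- make_test_cohort(n_subjects = 3, speeds = 1.0, duration = 12,
                          noise_sd = 0.1, seed = 54)
  # train_power_model records provenance; run_inter_subject asserts on it
  model <- train_power_model(coh[c(1, 2)], power_config(seed = 1))
  expect_setequal(model$subjects, c("S1", "S2"))
  expect_false("S3" %in% model$subjects)
})

test_that("reports aggregate per speed and overall with cycle counts", {
  coh <- make_test_cohort(n_subjects = 2, speeds = c(0.7, 1.3), duration = 12,
                          noise_sd = 0.1, seed = 55)
  rep <- run_intra_subject(coh, power_config(seed = 8))
  expect_equal(nrow(rep$cells), 4)
  expect_equal(nrow(rep$per_speed), 2)
  expect_equal(rep$per_speed$speed, c(0.7, 1.3))
  expect_equal(rep$aggregate$R, mean(rep$cells$R))
  expect_equal(rep$aggregate$n_cycles, sum(rep$cells$n_cycles))
  expect_output(print(rep), "Intra-subject")
})
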