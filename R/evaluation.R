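#' Regression accuracy metrics
#'
#' Pearson correlation (R), root mean squared error (RMSE, w/kg) and the
#' normalised RMSE in percent. NRMSE normalises by the range (max - min) of
#' the reference series by default; `denominator = "mean"` or `"max"` select
#' the alternatives.
#'
#' @param y_true reference power series (w/kg), non-constant.
#' @param y_pred predicted power series, same length.
#' @param denominator NRMSE normaliser: `"range"` (default), `"mean"` or
#'   `"max"`.
#' @return named list with `R`, `RMSE`, `NRMSE`.
#' @export
regression_metrics <- function(y_true, y_pred,
                               denominator = c("range", "mean", "max")) {
  denominator <- match.arg(denominator)
  if (length(y_true) != length(y_pred)) stop("series lengths differ")
  if (length(y_true) < 2) stop("need at least 2 samples")
  if (max(y_true) == min(y_true)) {
    stop("R undefined: `y_true` is constant")
  }
  rmse <- sqrt(mean((y_pred - y_true)^2))
  denom <- switch(denominator,
    range = max(y_true) - min(y_true),
    mean = mean(y_true),
    max = max(y_true)
  )
  list(
    R = stats::cor(y_true, y_pred),
    RMSE = rmse,
    NRMSE = 100 * rmse / denom
  )
}

#' Per-cycle peak power and its occurrence
#'
#' For every gait cycle, reports the maximum of the power series over the
#' cycle span and its position as a percentage of the cycle duration
#' (`100 * (argmax - start) / (end - start)`; the first index wins ties).
#' Cycles with a constant power trace are flagged degenerate; their
#' occurrence is reported as 0 but should be excluded from occurrence
#' averages.
#'
#' @param power numeric power series (w/kg).
#' @param cycles a [segment_gait_cycles()] result (or data.frame with
#'   `start`, `end`) indexing into `power`.
#' @return data.frame with one row per cycle: `peak`, `occurrence`,
#'   `degenerate`.
#' @export
peak_analysis <- function(power, cycles) {
  if (nrow(cycles) == 0) {
    return(data.frame(peak = numeric(0), occurrence = numeric(0),
                      degenerate = logical(0)))
  }
  if (max(cycles$end) - 1 > length(power) || min(cycles$start) < 1) {
    stop("cycles index outside the power series")
  }
  out <- lapply(seq_len(nrow(cycles)), function(k) {
    span <- cycles$start[k]:(cycles$end[k] - 1)
    seg <- power[span]
    i <- which.max(seg)
    data.frame(
      peak = seg[i],
      occurrence = 100 * (i - 1) / length(seg),
      degenerate = max(seg) == min(seg)
    )
  })
  do.call(rbind, out)
}

#' Relative peak power error
#'
#' `100 * (predicted peak - true peak) / power range`, the peak amplitude
#' error expressed as a percentage of the valley-to-peak power range.
#'
#' @param pred_peak predicted peak power (w/kg).
#' @param true_peak reference peak power (w/kg).
#' @param power_range valley-to-peak range of the reference power (w/kg),
#'   strictly positive.
#' @return signed percentage.
#' @export
relative_peak_error <- function(pred_peak, true_peak, power_range) {
  if (any(power_range <= 0)) stop("`power_range` must be positive")
  100 * (pred_peak - true_peak) / power_range
}

# Evaluate a trained model on the test span [test_from, test_to] of a trial:
# calibrate on the first half of the span, score on the second half (or the
# full span under eval_span = "full_test"). Returns one row of cell metrics.
evaluate_segment <- function(model, trial, test_from, test_to, config) {
  test_trial <- trial_slice(trial, test_from, test_to)
  fm <- trial_features(test_trial, config, stride = 1)
  x <- fm$values
  if (!is.null(model$scaling)) x <- apply_scaling(x, model$scaling)
  centers_abs <- fm$center + (test_from - 1L)
  cal_end_abs <- test_from - 1L + (test_to - test_from + 1L) %/% 2L
  cal_rows <- which(centers_abs <= cal_end_abs)
  eval_rows <- if (identical(config$eval_span, "full_test")) {
    seq_along(centers_abs)
  } else {
    which(centers_abs > cal_end_abs)
  }
  if (length(cal_rows) < 2 || length(eval_rows) < 2) {
    stop("test span too short to calibrate and evaluate")
  }
  pool <- qrf_pool(model$forest, x)
  raw <- vapply(pool, function(p) weighted_quantile(p$v, p$w, 0.5), numeric(1))
  calibration <- if (identical(config$calibration_source, "reference")) {
    fit_calibration(fm$target[cal_rows])
  } else {
    fit_calibration(raw[cal_rows])
  }
  qn <- calibration_probability(raw[eval_rows], calibration)
  pred <- vapply(seq_along(eval_rows), function(i) {
    p <- pool[[eval_rows[i]]]
    weighted_quantile(p$v, p$w, qn[i])
  }, numeric(1))
  y_true <- fm$target[eval_rows]
  metrics <- regression_metrics(y_true, pred,
                                denominator = config$nrmse_denominator)
  # Peak analysis over complete gait cycles inside the evaluated span.
  eval_abs <- centers_abs[eval_rows]
  grf_seg <- trial$data$grf[eval_abs[1]:eval_abs[length(eval_abs)]]
  cycles <- segment_gait_cycles(grf_seg, threshold = config$grf_threshold,
                                min_stance = config$min_stance)
  power_range <- max(y_true) - min(y_true)
  if (nrow(cycles) > 0) {
    true_pk <- peak_analysis(y_true, cycles)
    pred_pk <- peak_analysis(pred, cycles)
    ok <- !true_pk$degenerate & !pred_pk$degenerate
    true_pk <- true_pk[ok, , drop = FALSE]
    pred_pk <- pred_pk[ok, , drop = FALSE]
  } else {
    true_pk <- pred_pk <- data.frame(peak = numeric(0), occurrence = numeric(0))
  }
  data.frame(
    subject = trial$subject_id,
    speed = trial$speed,
    R = metrics$R,
    RMSE = metrics$RMSE,
    NRMSE = metrics$NRMSE,
    true_peak = mean(true_pk$peak),
    pred_peak = mean(pred_pk$peak),
    true_occurrence = mean(true_pk$occurrence),
    pred_occurrence = mean(pred_pk$occurrence),
    rel_peak_error = relative_peak_error(mean(pred_pk$peak),
                                         mean(true_pk$peak), power_range),
    n_cycles = nrow(true_pk),
    n_samples = length(eval_rows)
  )
}

# Aggregate per-cell metrics into per-speed rows and one overall row
# (unweighted means over subject x speed cells).
build_eval_report <- function(cells, protocol) {
  metric_cols <- c("R", "RMSE", "NRMSE", "true_peak", "pred_peak",
                   "true_occurrence", "pred_occurrence", "rel_peak_error")
  agg <- function(rows) {
    out <- as.data.frame(lapply(rows[metric_cols], mean))
    out$n_cycles <- sum(rows$n_cycles)
    out$n_samples <- sum(rows$n_samples)
    out
  }
  per_speed <- do.call(rbind, lapply(split(cells, cells$speed), agg))
  per_speed <- cbind(speed = as.numeric(rownames(per_speed)), per_speed)
  rownames(per_speed) <- NULL
  structure(list(
    protocol = protocol,
    cells = cells,
    per_speed = per_speed,
    aggregate = agg(cells)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("%s-subject evaluation (%d subject-speed cells)\n",
              if (x$protocol == "intra") "Intra" else "Inter",
              nrow(x$cells)))
  cat("Per speed:\n")
  print(format(x$per_speed, digits = digits), row.names = FALSE)
  cat("Aggregate:\n")
  print(format(x$aggregate, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Intra-subject (subject-dependent) evaluation protocol
#'
#' For each subject, trains one model on the first half of every trial of
#' that subject, then evaluates on the held-out second halves: within each
#' test half, the first portion calibrates the quantile-probability mapping
#' and the second portion is scored. Metrics are aggregated as unweighted
#' means over subject-speed cells, with a per-speed breakdown.
#'
#' @param cohort a `gait_cohort` (or list of [gait_trial()]s with reference
#'   power).
#' @param config a [power_config()].
#' @return an `eval_report` with protocol tag `"intra"`.
#' @export
run_intra_subject <- function(cohort, config = power_config()) {
  subjects <- unique(vapply(cohort, function(tr) tr$subject_id, character(1)))
  cells <- list()
  for (s in subjects) {
    trials_s <- Filter(function(tr) tr$subject_id == s, cohort)
    splits <- vapply(trials_s, function(tr) {
      as.integer(floor(nrow(tr$data) * config$train_fraction))
    }, integer(1))
    usable <- splits >= 2 * window_spec(config$window_ms,
                                        sample_rate = trials_s[[1]]$sample_rate)$length_samples
    if (any(!usable)) {
      warning(sprintf("subject %s: skipping %d trial(s) too short to split",
                      s, sum(!usable)))
    }
    trials_s <- trials_s[usable]
    splits <- splits[usable]
    if (length(trials_s) == 0) next
    train_halves <- Map(function(tr, k) trial_slice(tr, 1, k),
                        trials_s, splits)
    model <- train_power_model(train_halves, config)
    for (i in seq_along(trials_s)) {
      cells[[length(cells) + 1L]] <- evaluate_segment(
        model, trials_s[[i]], splits[i] + 1L, nrow(trials_s[[i]]$data),
        config)
    }
  }
  build_eval_report(do.call(rbind, cells), "intra")
}

#' Inter-subject (leave-one-subject-out) evaluation protocol
#'
#' Each subject in turn is held out: a model is trained on all trials of the
#' remaining subjects, and every trial of the held-out subject is evaluated —
#' its first half calibrates the quantile-probability mapping and only its
#' second half is scored. Metrics are aggregated as in
#' [run_intra_subject()].
#'
#' @param cohort a `gait_cohort` with at least 3 subjects.
#' @param config a [power_config()].
#' @return an `eval_report` with protocol tag `"inter"`.
#' @export
run_inter_subject <- function(cohort, config = power_config()) {
  subjects <- unique(vapply(cohort, function(tr) tr$subject_id, character(1)))
  if (length(subjects) < 3) stop("need at least 3 subjects")
  cells <- list()
  for (s in subjects) {
    train_trials <- Filter(function(tr) tr$subject_id != s, cohort)
    test_trials <- Filter(function(tr) tr$subject_id == s, cohort)
    model <- train_power_model(train_trials, config)
    stopifnot(!(s %in% model$subjects))
    for (tr in test_trials) {
      cells[[length(cells) + 1L]] <- evaluate_segment(
        model, tr, 1L, nrow(tr$data), config)
    }
  }
  build_eval_report(do.call(rbind, cells), "inter")
}
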