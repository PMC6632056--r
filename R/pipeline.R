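#' Pipeline configuration
#'
#' Collects every tunable of the estimation pipeline with its default:
#' preprocessing (`median_window`, `lowpass_cutoff_hz`, `lowpass_order`,
#' `scaling`), feature extraction (`window_ms`, `stride`, `ssc_threshold`,
#' `mav_mode`, `db7_level`), the forest (`n_trees`, `min_leaf`, `mtry`,
#' `candidates`, `seed`), calibration (`calibration_source`), segmentation
#' (`grf_threshold`, `min_stance`) and the evaluation protocols
#' (`train_fraction`, `train_stride`, `eval_span`, `nrmse_denominator`,
#' `smooth_reference`).
#'
#' `train_stride` thins the rows used for forest training only (prediction
#' is always dense); raising it trades a little accuracy for a large drop in
#' training time on big cohorts.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `power_config`.
#' @export
power_config <- function(...) {
  config <- list(
    median_window = 5,
    lowpass_cutoff_hz = 6,
    lowpass_order = 4,
    scaling = "minmax",           # minmax | none
    window_ms = 110,
    stride = 1,
    ssc_threshold = 0,
    mav_mode = "absolute",        # absolute | about_mean
    db7_level = 1,
    n_trees = 50,
    min_leaf = 5,
    mtry = NULL,
    candidates = "pooled",        # pooled | trees
    seed = 1,
    calibration_source = "predicted",  # predicted | reference
    grf_threshold = 0,
    min_stance = 10,
    train_fraction = 0.5,
    train_stride = 1,
    eval_span = "second_half",    # second_half | full_test
    nrmse_denominator = "range",  # range | mean | max
    smooth_reference = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  config[names(overrides)] <- overrides
  structure(config, class = "power_config")
}

#' @export
print.power_config <- function(x, ...) {
  cat("Power estimation config:\n")
  for (key in names(x)) {
    cat(sprintf("  %-20s %s\n", key,
                if (is.null(x[[key]])) "auto" else paste(x[[key]], collapse = ", ")))
  }
  invisible(x)
}

# Median-filter the IMU channels (and optionally low-pass the reference
# power) of a trial.
preprocess_trial <- function(trial, config) {
  for (ch in imu_channel_names()) {
    trial$data[[ch]] <- median_filter(trial$data[[ch]], config$median_window)
  }
  if (isTRUE(config$smooth_reference) && "power" %in% names(trial$data)) {
    trial$data$power <- butterworth_lowpass(
      trial$data$power, cutoff = config$lowpass_cutoff_hz,
      order = config$lowpass_order, sample_rate = trial$sample_rate)
  }
  trial
}

# Preprocess a trial and extract its feature matrix.
trial_features <- function(trial, config, stride = config$stride) {
  trial <- preprocess_trial(trial, config)
  spec <- window_spec(length_ms = config$window_ms, stride = stride,
                      sample_rate = trial$sample_rate)
  build_feature_matrix(trial, spec, ssc_threshold = config$ssc_threshold,
                       mav_mode = config$mav_mode,
                       db7_level = config$db7_level)
}

#' Train a power estimation model on a set of trials
#'
#' Runs the full training pipeline: median-filters the IMU channels, extracts
#' windowed features from every trial, fits min-max scaling on the pooled
#' training rows, and trains the quantile regression forest on the scaled
#' features against the reference power at the window centres.
#'
#' @param trials a list of [gait_trial()]s (or a `gait_cohort`) carrying
#'   reference power.
#' @param config a [power_config()].
#' @return object of class `power_model` holding the forest, the scaling
#'   parameters, the config and the training subject ids.
#' @export
train_power_model <- function(trials, config = power_config()) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  fms <- lapply(trials, trial_features, config = config,
                stride = config$train_stride)
  x <- do.call(rbind, lapply(fms, function(fm) fm$values))
  y <- unlist(lapply(fms, function(fm) fm$target), use.names = FALSE)
  if (is.null(y) || length(y) == 0) {
    stop("training trials must carry a reference power column")
  }
  scaling <- NULL
  if (identical(config$scaling, "minmax")) {
    scaling <- fit_scaling(x)
    x <- apply_scaling(x, scaling)
  }
  forest <- train_forest(x, y, n_trees = config$n_trees,
                         min_leaf = config$min_leaf, mtry = config$mtry,
                         seed = config$seed, candidates = config$candidates)
  structure(list(
    forest = forest,
    scaling = scaling,
    config = config,
    subjects = unique(vapply(trials, function(tr) tr$subject_id, character(1)))
  ), class = "power_model")
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("Power estimation model: trained on subjects %s\n",
              paste(x$subjects, collapse = ", ")))
  print(x$forest)
  invisible(x)
}

#' Estimate the power trace of a trial
#'
#' Extracts features densely (stride 1), applies the model's scaling, and
#' predicts power at every window centre — raw median predictions by
#' default, calibrated predictions when a calibration is supplied.
#'
#' @param model a [train_power_model()] model.
#' @param trial a [gait_trial()].
#' @param calibration optional [fit_calibration()] object.
#' @return data.frame with columns `index` (centre sample in the trial),
#'   `time`, `power` (predicted, w/kg) and, when the trial carries reference
#'   power, `reference`.
#' @export
predict_power <- function(model, trial, calibration = NULL) {
  stopifnot(inherits(model, "power_model"))
  fm <- trial_features(trial, model$config, stride = 1)
  x <- fm$values
  if (!is.null(model$scaling)) x <- apply_scaling(x, model$scaling)
  pred <- if (is.null(calibration)) {
    predict_quantile(model$forest, x, 0.5)
  } else {
    predict_calibrated(model$forest, x, calibration)
  }
  out <- data.frame(index = fm$center, time = fm$time, power = pred)
  if (!is.null(fm$target)) out$reference <- fm$target
  out
}
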