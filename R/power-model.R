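#' Train a quantile regression forest
#'
#' Grows a random forest of regression trees (bootstrap resampling, random
#' feature subsetting at each split) and retains the in-bag training
#' responses of every leaf, so that arbitrary conditional quantiles — not
#' just the mean — can be predicted. Forest growing is delegated to
#' \pkg{ranger} (single-threaded, seeded, with a minimum terminal-node size
#' so every leaf holds at least `min_leaf` responses); the leaf-response
#' bookkeeping and quantile machinery are implemented here.
#'
#' @param features a [build_feature_matrix()] result carrying targets, or a
#'   plain numeric matrix.
#' @param target response vector (w/kg); taken from `features$target` when
#'   omitted.
#' @param n_trees number of trees (default 50).
#' @param min_leaf minimum number of training responses per leaf (default 5).
#' @param mtry number of candidate features per split; default
#'   `ceiling(p/3)`, the regression convention.
#' @param seed integer seed making training deterministic.
#' @param candidates `"pooled"` (default): the candidate response set of a
#'   prediction is the pooled weighted leaf-response distribution, quantile
#'   regression forest style. `"trees"`: one candidate per tree, its reached
#'   leaf's mean response.
#' @return object of class `quantile_forest`.
#' @export
train_forest <- function(features, target = NULL, n_trees = 50, min_leaf = 5,
                         mtry = NULL, seed = 1,
                         candidates = c("pooled", "trees")) {
  candidates <- match.arg(candidates)
  x <- feature_values(features)
  if (is.null(target) && inherits(features, "feature_matrix")) {
    target <- features$target
  }
  if (is.null(target)) stop("no training targets supplied")
  if (any(!is.finite(target))) stop("targets must be finite")
  if (nrow(x) < min_leaf) {
    stop(sprintf("need at least %d training rows (got %d)", min_leaf, nrow(x)))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(mtry)) mtry <- ceiling(ncol(x) / 3)
  rf <- ranger::ranger(
    x = x, y = target,
    num.trees = n_trees,
    min.node.size = min_leaf,
    min.bucket = min_leaf,
    mtry = min(mtry, ncol(x)),
    replace = TRUE,
    keep.inbag = TRUE,
    seed = seed,
    num.threads = 1,
    oob.error = FALSE
  )
  tn <- stats::predict(rf, x, type = "terminalNodes",
                       num.threads = 1)$predictions
  inbag <- matrix(unlist(rf$inbag.counts), ncol = n_trees)
  leaf_values <- lapply(seq_len(n_trees), function(t) {
    reps <- inbag[, t]
    split(rep(target, reps), rep(tn[, t], reps))
  })
  structure(list(
    forest = rf,
    leaf_values = leaf_values,
    n_trees = n_trees,
    min_leaf = min_leaf,
    mtry = mtry,
    seed = seed,
    candidates = candidates,
    feature_names = colnames(x)
  ), class = "quantile_forest")
}

#' @export
print.quantile_forest <- function(x, ...) {
  cat(sprintf("Quantile regression forest: %d trees, min leaf %d, %d features (%s candidates)\n",
              x$n_trees, x$min_leaf, length(x$feature_names), x$candidates))
  invisible(x)
}

# Pool the candidate-response distribution of each row: the reached leaf's
# responses in every tree, each weighted 1/(n_trees * leaf size) ("pooled"),
# or one per-tree leaf mean with weight 1/n_trees ("trees").
qrf_pool <- function(model, x) {
  x <- feature_values(x)
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature schema mismatch with the training columns")
  }
  tn <- stats::predict(model$forest, x, type = "terminalNodes",
                       num.threads = 1)$predictions
  nt <- model$n_trees
  lapply(seq_len(nrow(x)), function(i) {
    leaves <- lapply(seq_len(nt), function(t) {
      model$leaf_values[[t]][[as.character(tn[i, t])]]
    })
    if (model$candidates == "trees") {
      list(v = vapply(leaves, mean, numeric(1)), w = rep(1 / nt, nt))
    } else {
      list(v = unlist(leaves, use.names = FALSE),
           w = rep(1 / (nt * lengths(leaves)), lengths(leaves)))
    }
  })
}

#' Candidate quantile of a set of reached leaves
#'
#' The elementary prediction rule of the quantile forest: given the response
#' sets of the leaves reached in each tree, pool them with each response
#' weighted by `1/(n_trees * leaf size)` and return the weighted empirical
#' quantile with linear interpolation (see [weighted_quantile()]).
#'
#' @param leaves list of numeric vectors, one per tree.
#' @param q quantile probability (vectorised).
#' @return numeric quantile value(s).
#' @export
pooled_quantile <- function(leaves, q) {
  nt <- length(leaves)
  weighted_quantile(
    unlist(leaves, use.names = FALSE),
    rep(1 / (nt * lengths(leaves)), lengths(leaves)),
    q
  )
}

#' Predict conditional quantiles
#'
#' For each row, pools the training responses of the leaf reached in every
#' tree and returns the weighted empirical quantile. `q = 0.5` is the
#' uncalibrated default prediction (the median of the candidate responses).
#'
#' @param model a [train_forest()] model.
#' @param x feature rows (matrix or [build_feature_matrix()] result) with the
#'   training column schema.
#' @param q quantile probability: a scalar, or a vector with one probability
#'   per row.
#' @return numeric vector of predicted power (w/kg), one value per row.
#' @export
predict_quantile <- function(model, x, q = 0.5) {
  stopifnot(inherits(model, "quantile_forest"))
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]")
  pool <- qrf_pool(model, x)
  if (length(q) == 1L) q <- rep(q, length(pool))
  if (length(q) != length(pool)) {
    stop("`q` must be a scalar or one probability per row")
  }
  vapply(seq_along(pool), function(i) {
    weighted_quantile(pool[[i]]$v, pool[[i]]$w, q[i])
  }, numeric(1))
}

#' Fit the quantile-probability calibration
#'
#' Records the extrema of the raw (median) predictions over a calibration
#' segment — typically the first half of a test trial. At prediction time
#' each raw prediction is min-max normalised by these extrema and the result
#' is used as the quantile probability of its own final prediction, boosting
#' peaks towards high quantiles and valleys towards low ones.
#'
#' @param raw_predictions numeric series of raw predictions (w/kg) on the
#'   calibration segment; must hold at least 2 distinct values.
#' @return object of class `quantile_calibration` with fields `cal_min`,
#'   `cal_max`.
#' @export
fit_calibration <- function(raw_predictions) {
  if (length(raw_predictions) < 2) {
    stop("calibration segment must hold at least 2 values")
  }
  lo <- min(raw_predictions)
  hi <- max(raw_predictions)
  if (hi <= lo) stop("calibration impossible: constant segment")
  structure(list(cal_min = lo, cal_max = hi), class = "quantile_calibration")
}

#' @export
print.quantile_calibration <- function(x, ...) {
  cat(sprintf("Quantile calibration: [%.4g, %.4g] w/kg\n", x$cal_min, x$cal_max))
  invisible(x)
}

#' Quantile probability assigned to a raw prediction
#'
#' Min-max normalises a raw prediction by the calibration extrema and clips
#' the result to \[0, 1\] (a quantile probability). A raw prediction of 1.5
#' under a \[0, 2\] calibration maps to 0.75, i.e. the 75th percentile of the
#' candidate responses is selected.
#'
#' @param raw numeric raw (median) predictions.
#' @param calibration a [fit_calibration()] object.
#' @return numeric probabilities in \[0, 1\].
#' @export
calibration_probability <- function(raw, calibration) {
  stopifnot(inherits(calibration, "quantile_calibration"))
  pmin(1, pmax(0, (raw - calibration$cal_min) /
                 (calibration$cal_max - calibration$cal_min)))
}

#' Predict calibrated power
#'
#' Two-pass prediction: the raw median prediction of each row is mapped to a
#' quantile probability via the calibration, and that quantile of the row's
#' own candidate distribution is returned. This is the mechanism that
#' corrects the forest's systematic underestimation of push-off power peaks.
#'
#' @param model a [train_forest()] model.
#' @param x feature rows.
#' @param calibration a [fit_calibration()] object.
#' @return numeric vector of calibrated power predictions (w/kg).
#' @export
predict_calibrated <- function(model, x, calibration) {
  stopifnot(inherits(model, "quantile_forest"))
  pool <- qrf_pool(model, x)
  raw <- vapply(pool, function(p) weighted_quantile(p$v, p$w, 0.5), numeric(1))
  qn <- calibration_probability(raw, calibration)
  vapply(seq_along(pool), function(i) {
    weighted_quantile(pool[[i]]$v, pool[[i]]$w, qn[i])
  }, numeric(1))
}
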