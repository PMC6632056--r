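#' Running median filter with shrinking edge windows
#'
#' Smooths a series with a centred running median. At the series edges, where
#' a full window does not fit, the window shrinks symmetrically to the
#' largest odd size available (so the first and last samples pass through
#' unchanged). Output length equals input length.
#'
#' @param x numeric series.
#' @param window odd window length in samples (default 5).
#' @return filtered series of the same length.
#' @export
median_filter <- function(x, window = 5) {
  if (length(window) != 1L || window < 1 || window %% 2 == 0) {
    stop("`window` must be a positive odd integer")
  }
  n <- length(x)
  if (window == 1 || n <= 2) return(x)
  h <- (window - 1) / 2
  if (n >= window) {
    out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
    edge <- seq_len(h)
  } else {
    out <- x
    edge <- seq_len(n)
  }
  for (i in edge) {
    k <- min(i - 1, n - i)
    out[i] <- stats::median(x[(i - k):(i + k)])
    j <- n - i + 1
    k <- min(j - 1, n - j)
    out[j] <- stats::median(x[(j - k):(j + k)])
  }
  out
}

# Steady-state initial filter state for a step input of unit height
# (direct-form-II-transposed), so filtering a constant yields that constant
# from the first sample on.
iir_steady_state <- function(b, a) {
  k <- max(length(a), length(b))
  a <- c(a, rep(0, k - length(a)))
  b <- c(b, rep(0, k - length(b)))
  comp <- matrix(0, k - 1, k - 1)
  comp[1, ] <- -a[2:k] / a[1]
  if (k > 2) comp[cbind(2:(k - 1), 1:(k - 2))] <- 1
  rhs <- b[2:k] - a[2:k] * b[1]
  solve(diag(k - 1) - t(comp), rhs)
}

# Direct-form-II-transposed IIR filter with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  k <- max(length(a), length(b))
  a <- c(a, rep(0, k - length(a)))
  b <- c(b, rep(0, k - length(b)))
  n <- length(x)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z[1]
    if (k > 2) {
      for (j in 1:(k - 2)) z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    }
    z[k - 1] <- b[k] * x[i] - a[k] * y[i]
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero phase, squared magnitude response). Edge transients are suppressed
#' by odd-reflection padding and steady-state initial conditions, so a
#' constant series passes through unchanged (DC gain 1).
#'
#' Used to smooth the reference joint-power trace before training and
#' evaluation; the conventional setting in gait analysis is a 4th-order
#' filter with a 6 Hz cut-off.
#'
#' @param x numeric series.
#' @param cutoff cut-off frequency in Hz (default 6).
#' @param order filter order (default 4).
#' @param sample_rate sampling rate in Hz.
#' @return filtered series of the same length.
#' @export
butterworth_lowpass <- function(x, cutoff = 6, order = 4, sample_rate) {
  if (cutoff <= 0 || cutoff >= sample_rate / 2) {
    stop("`cutoff` must lie strictly between 0 and the Nyquist frequency")
  }
  n <- length(x)
  if (n < 2) return(x)
  bf <- signal::butter(order, 2 * cutoff / sample_rate, type = "low")
  b <- bf$b
  a <- bf$a
  p <- min(3 * (max(length(a), length(b)) - 1), n - 1)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  zi <- iir_steady_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(p + 1):(p + n)]
}

#' Fit per-column min-max scaling parameters
#'
#' Records the column-wise minimum and maximum of a feature matrix fit set.
#' Columns whose minimum equals their maximum are flagged constant and later
#' map to 0.
#'
#' @param features numeric matrix (or [feature_matrix]) with named columns.
#' @return an object of class `scaling_params` with fields `min`, `max`,
#'   `constant`.
#' @seealso [apply_scaling()]
#' @export
fit_scaling <- function(features) {
  x <- feature_values(features)
  if (nrow(x) == 0L) stop("cannot fit scaling on an empty matrix")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(
    list(min = mins, max = maxs, constant = maxs == mins),
    class = "scaling_params"
  )
}

#' Apply min-max scaling
#'
#' Maps each column through `(x - min) / (max - min)` using parameters fit on
#' a (typically training) set. Values outside the fitted range extrapolate
#' beyond \[0, 1\] and are deliberately not clipped; constant columns map
#' to 0.
#'
#' @param features numeric matrix (or [feature_matrix]) with columns matching
#'   the fit set.
#' @param params a `scaling_params` object from [fit_scaling()].
#' @return object of the same shape with scaled values.
#' @export
apply_scaling <- function(features, params) {
  stopifnot(inherits(params, "scaling_params"))
  x <- feature_values(features)
  if (!identical(colnames(x), names(params$min))) {
    stop("feature columns do not match the scaling parameters")
  }
  rng <- params$max - params$min
  rng[params$constant] <- 1
  scaled <- sweep(sweep(x, 2, params$min, "-"), 2, rng, "/")
  if (inherits(features, "feature_matrix")) {
    features$values <- scaled
    features
  } else {
    scaled
  }
}

# Accept either a bare matrix or a feature_matrix.
feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("Min-max scaling parameters:", length(x$min), "columns,",
      sum(x$constant), "constant\n")
  invisible(x)
}
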