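# Daubechies-7 decomposition high-pass filter (14 taps), exact to double
# precision. The low-pass filter follows from the quadrature-mirror relation.
.db7_dec_hi <- c(
  -0.077852054085009184, 0.39653931948191729, -0.72913209084623509,
  0.46978228740519312, 0.14390600392856498, -0.22403618499387498,
  -0.071309219266830259, 0.080612609151083078, 0.038029936935014413,
  -0.016574541630666881, -0.01255099855609984, 0.00042957797292136651,
  0.0018016407040474908, 0.00035371379997452024
)
.db7_dec_lo <- rev(.db7_dec_hi) * rep(c(1, -1), length.out = 14)

# Half-sample symmetric boundary fold: maps any integer position onto 1..n
# by repeated reflection (... x3 x2 x1 | x1 x2 ... xn | xn xn-1 ...).
sym_fold <- function(t, n) {
  m <- 2L * n
  t <- ((t - 1L) %% m + m) %% m + 1L
  ifelse(t <= n, t, m - t + 1L)
}

# One analysis step of the discrete wavelet transform with symmetric
# extension: convolve with `h` and downsample by two. Output length
# floor((n + L - 1) / 2), matching the standard symmetric-mode convention.
dwt_step <- function(x, h) {
  n <- length(x)
  len <- length(h)
  ext <- x[sym_fold(seq(2L - len, n + len - 1L), n)]
  cv <- stats::convolve(ext, rev(h), type = "open")
  cv[seq(len + 1L, by = 2L, length.out = (n + len - 1L) %/% 2L)]
}

# Level-k db7 detail coefficients (approximation cascade then one detail
# step).
db7_detail <- function(x, level = 1L) {
  if (level > 1L) {
    for (i in seq_len(level - 1L)) x <- dwt_step(x, .db7_dec_lo)
  }
  dwt_step(x, .db7_dec_hi)
}

#' Names of the 13 window features, in canonical order
#'
#' @return character vector: RMS, SAV, MAV, VAR, WL, SSC, SSI, DB7, DASDV,
#'   AAC, LD, LF, PF.
#' @export
feature_names <- function() {
  c("RMS", "SAV", "MAV", "VAR", "WL", "SSC", "SSI", "DB7", "DASDV", "AAC",
    "LD", "LF", "PF")
}

#' Sliding-window specification for feature extraction
#'
#' The window length in samples is `round(length_ms * sample_rate / 1000)`,
#' forced odd so every window has a well-defined centre sample (11 samples
#' for the default 110 ms at 100 Hz).
#'
#' @param length_ms window length in milliseconds (default 110).
#' @param stride hop between window centres in samples (default 1, dense).
#' @param sample_rate sampling rate in Hz.
#' @return object of class `window_spec` with the derived `length_samples`.
#' @export
window_spec <- function(length_ms = 110, stride = 1, sample_rate = 100) {
  stopifnot(length_ms > 0, stride >= 1, sample_rate > 0)
  n <- round(length_ms * sample_rate / 1000)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, 3)
  structure(list(length_ms = length_ms, stride = as.integer(stride),
                 sample_rate = sample_rate, length_samples = as.integer(n)),
            class = "window_spec")
}

#' Extract the 13 time-domain features from one window
#'
#' Computes, in the order of [feature_names()]: root mean square (RMS), sum
#' of absolute values (SAV), mean absolute value (MAV = SAV/N; set
#' `mav_mode = "about_mean"` for mean absolute deviation about the window
#' mean), sample variance (VAR, N-1 denominator), waveform length (WL, sum
#' of absolute successive differences), slope sign changes (SSC), simple
#' square integral (SSI), mean absolute level-`db7_level` detail coefficient
#' of a Daubechies-7 wavelet transform with symmetric extension (DB7),
#' difference absolute standard deviation value (DASDV), average amplitude
#' change (AAC = WL/(N-1)), log detector (LD, exponential of the mean
#' log-magnitude), the least-squares line slope over sample index (LF), and
#' the leading coefficient of the least-squares parabola (PF).
#'
#' These are the time-domain descriptors established in EMG pattern
#' recognition, applied here to IMU channels.
#'
#' @param w numeric window of at least 3 samples.
#' @param ssc_threshold minimum magnitude both neighbouring slopes must reach
#'   for a slope sign change to count (default 0: any strict sign change).
#' @param mav_mode `"absolute"` (default) or `"about_mean"`.
#' @param db7_level wavelet decomposition level for DB7 (default 1).
#' @return named numeric vector of length 13.
#' @export
extract_window_features <- function(w, ssc_threshold = 0,
                                    mav_mode = c("absolute", "about_mean"),
                                    db7_level = 1) {
  mav_mode <- match.arg(mav_mode)
  if (length(w) < 3) stop("window must hold at least 3 samples")
  bad <- which(!is.finite(w))
  if (length(bad) > 0) {
    stop(sprintf("non-finite value at sample %d of the window", bad[[1L]]))
  }
  n <- length(w)
  d <- diff(w)
  idx <- seq_len(n) - 1
  ssi <- sum(w^2)
  sav <- sum(abs(w))
  wl <- sum(abs(d))
  sl <- stats::cov(idx, w) / stats::var(idx)
  quad <- stats::lm.fit(cbind(1, idx, idx^2), w)$coefficients[[3L]]
  c(
    RMS = sqrt(ssi / n),
    SAV = sav,
    MAV = if (mav_mode == "absolute") sav / n else mean(abs(w - mean(w))),
    VAR = stats::var(w),
    WL = wl,
    SSC = sum(d[-(n - 1)] * d[-1] < 0 &
                abs(d[-(n - 1)]) >= ssc_threshold &
                abs(d[-1]) >= ssc_threshold),
    SSI = ssi,
    DB7 = mean(abs(db7_detail(w, db7_level))),
    DASDV = sqrt(sum(d^2) / (n - 1)),
    AAC = wl / (n - 1),
    LD = exp(mean(log(abs(w) + 1e-12))),
    LF = sl,
    PF = quad
  )
}

# Linear operator computing level-`level` db7 detail coefficients of an
# n-sample window, so the wavelet feature vectorises to a matrix product.
db7_operator <- function(n, level = 1L) {
  vapply(seq_len(n), function(j) {
    e <- numeric(n)
    e[j] <- 1
    db7_detail(e, level)
  }, db7_detail(numeric(n), level))
}

#' Build the windowed feature matrix of a trial
#'
#' Slides the feature window over every IMU channel and concatenates the 13
#' features of all 12 channels into one row per window position (156 named
#' columns, `<channel>__<feature>`). Rows are aligned to the window-centre
#' sample; when the trial carries reference power, the value at the centre
#' sample is attached as the regression target.
#'
#' @param trial a [gait_trial()] holding all 12 IMU channels.
#' @param spec a [window_spec()]; its sample rate must match the trial's.
#' @param ssc_threshold,mav_mode,db7_level passed to the feature definitions
#'   (see [extract_window_features()]).
#' @return object of class `feature_matrix`: list with `values` (numeric
#'   matrix), `center` (1-based centre sample indices into the trial),
#'   `time`, and `target` (reference power at the centres, or `NULL`).
#' @export
build_feature_matrix <- function(trial, spec = window_spec(sample_rate = trial$sample_rate),
                                 ssc_threshold = 0, mav_mode = "absolute",
                                 db7_level = 1) {
  stopifnot(inherits(trial, "gait_trial"), inherits(spec, "window_spec"))
  nw <- spec$length_samples
  data <- trial$data
  n <- nrow(data)
  if (n < nw) stop("trial is shorter than one feature window")
  channels <- imu_channel_names()
  h <- (nw - 1L) %/% 2L
  pos <- seq(1L, n - nw + 1L, by = spec$stride)   # window start indices
  centers <- pos + h
  idx <- seq_len(nw) - 1
  cc <- idx - mean(idx)
  lf_vec <- cc / sum(cc^2)
  tmat <- cbind(1, idx, idx^2)
  pf_vec <- solve(crossprod(tmat), t(tmat))[3L, ]
  wop <- db7_operator(nw, db7_level)
  blocks <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    x <- data[[channels[ci]]]
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      stop(sprintf("non-finite value in channel '%s' at sample %d",
                   channels[ci], bad[[1L]]))
    }
    e <- stats::embed(x, nw)[, nw:1, drop = FALSE]   # rows = chronological windows
    e <- e[pos, , drop = FALSE]
    d <- e[, -1L, drop = FALSE] - e[, -nw, drop = FALSE]
    ssi <- rowSums(e^2)
    sav <- rowSums(abs(e))
    mu <- rowMeans(e)
    wl <- rowSums(abs(d))
    d1 <- d[, -(nw - 1L), drop = FALSE]
    d2 <- d[, -1L, drop = FALSE]
    feats <- cbind(
      RMS = sqrt(ssi / nw),
      SAV = sav,
      MAV = if (mav_mode == "absolute") sav / nw else rowMeans(abs(e - mu)),
      VAR = (ssi - nw * mu^2) / (nw - 1),
      WL = wl,
      SSC = rowSums(d1 * d2 < 0 & abs(d1) >= ssc_threshold &
                      abs(d2) >= ssc_threshold),
      SSI = ssi,
      DB7 = rowMeans(abs(e %*% t(wop))),
      DASDV = sqrt(rowSums(d^2) / (nw - 1)),
      AAC = wl / (nw - 1),
      LD = exp(rowMeans(log(abs(e) + 1e-12))),
      LF = as.numeric(e %*% lf_vec),
      PF = as.numeric(e %*% pf_vec)
    )
    colnames(feats) <- paste(channels[ci], colnames(feats), sep = "__")
    blocks[[ci]] <- feats
  }
  values <- do.call(cbind, blocks)
  structure(list(
    values = values,
    center = centers,
    time = data$time[centers],
    target = if ("power" %in% names(data)) data$power[centers] else NULL
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d windows x %d columns%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$target)) ", with targets" else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)
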