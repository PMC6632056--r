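# Independent brute-force oracles used to check the vectorised
# implementations. Everything here is written as plain loops over the
# mathematical definitions, sharing no code with the package internals.

# db7 decomposition filters, copied from the published coefficient tables.
oracle_db7_hi <- c(
  -0.077852054085009184, 0.39653931948191729, -0.72913209084623509,
  0.46978228740519312, 0.14390600392856498, -0.22403618499387498,
  -0.071309219266830259, 0.080612609151083078, 0.038029936935014413,
  -0.016574541630666881, -0.01255099855609984, 0.00042957797292136651,
  0.0018016407040474908, 0.00035371379997452024
)
oracle_db7_lo <- rev(oracle_db7_hi) * (-1)^(seq_along(oracle_db7_hi))
  # QMF relation lo[k] = (-1)^k hi[L+1-k]; sign convention fixed below.
oracle_db7_lo <- oracle_db7_lo * sign(sum(oracle_db7_lo))  # low-pass sums to +sqrt(2)

# Half-sample symmetric extension built by explicit tiling, then a direct
# double-loop convolution and decimation by two.
oracle_dwt_step <- function(x, h) {
  n <- length(x)
  len <- length(h)
  tile <- c(x, rev(x))  # period-2n pattern of the symmetric extension
  at <- function(t) tile[(t - 1) %% (2 * n) + 1]
  n_out <- (n + len - 1) %/% 2
  out <- numeric(n_out)
  for (k in seq_len(n_out)) {
    acc <- 0
    for (j in seq_len(len)) {
      # full convolution index 2k + len - 1, extension starts at 2 - len
      acc <- acc + h[j] * at((2 * k + len - 1) - j + 1 + (1 - len))
    }
    out[k] <- acc
  }
  out
}

oracle_db7 <- function(w, level = 1) {
  x <- w
  if (level > 1) {
    for (i in seq_len(level - 1)) x <- oracle_dwt_step(x, oracle_db7_lo)
  }
  mean(abs(oracle_dwt_step(x, oracle_db7_hi)))
}

# The 13 features, each from its printed definition, loop style.
oracle_features <- function(w) {
  n <- length(w)
  ssi <- 0; sav <- 0
  for (v in w) { ssi <- ssi + v^2; sav <- sav + abs(v) }
  mu <- sum(w) / n
  varr <- sum((w - mu)^2) / (n - 1)
  wl <- 0; dasdv2 <- 0
  for (i in 1:(n - 1)) {
    wl <- wl + abs(w[i + 1] - w[i])
    dasdv2 <- dasdv2 + (w[i + 1] - w[i])^2
  }
  ssc <- 0
  for (i in 2:(n - 1)) {
    if ((w[i] - w[i - 1]) * (w[i + 1] - w[i]) < 0) ssc <- ssc + 1
  }
  ld <- exp(sum(log(abs(w) + 1e-12)) / n)
  fit1 <- stats::lm(w ~ t, data = data.frame(t = 0:(n - 1), w = w))
  fit2 <- stats::lm(w ~ t + I(t^2), data = data.frame(t = 0:(n - 1), w = w))
  c(RMS = sqrt(ssi / n), SAV = sav, MAV = sav / n, VAR = varr, WL = wl,
    SSC = ssc, SSI = ssi, DB7 = oracle_db7(w),
    DASDV = sqrt(dasdv2 / (n - 1)), AAC = wl / (n - 1), LD = ld,
    LF = unname(stats::coef(fit1)[2]), PF = unname(stats::coef(fit2)[3]))
}

# Weighted empirical quantile by explicit enumeration: place order statistic
# i at position (weight strictly below i) / (total - weight of the largest),
# then scan for the bracketing pair and interpolate by hand.
oracle_weighted_quantile <- function(v, w, q) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  n <- length(v)
  if (n == 1) return(v)
  s <- sum(w)
  p <- numeric(n)
  for (i in seq_len(n)) {
    below <- if (i == 1) 0 else sum(w[1:(i - 1)])
    p[i] <- below / (s - w[n])
  }
  sapply(q, function(qq) {
    if (qq <= p[1]) return(v[1])
    if (qq >= p[n]) return(v[n])
    i <- max(which(p <= qq))
    if (p[i + 1] == p[i]) return(v[i])
    v[i] + (v[i + 1] - v[i]) * (qq - p[i]) / (p[i + 1] - p[i])
  })
}

# Pooled candidate quantile of a fitted quantile_forest, re-deriving the
# leaf memberships from the ranger object itself (terminal nodes of the
# training rows + in-bag counts), independent of the package's bookkeeping.
oracle_forest_quantile <- function(model, x_train, y_train, x_new, q) {
  tn_train <- predict(model$forest, x_train, type = "terminalNodes",
                      num.threads = 1)$predictions
  tn_new <- predict(model$forest, x_new, type = "terminalNodes",
                    num.threads = 1)$predictions
  inbag <- matrix(unlist(model$forest$inbag.counts), ncol = model$n_trees)
  nt <- model$n_trees
  out <- matrix(NA_real_, nrow(x_new), length(q))
  for (i in seq_len(nrow(x_new))) {
    v <- numeric(0); w <- numeric(0)
    for (t in seq_len(nt)) {
      members <- which(tn_train[, t] == tn_new[i, t])
      reps <- inbag[members, t]
      resp <- rep(y_train[members], reps)
      v <- c(v, resp)
      w <- c(w, rep(1 / (nt * length(resp)), length(resp)))
    }
    out[i, ] <- oracle_weighted_quantile(v, w, q)
  }
  out
}

# Small noiseless cohort for pipeline tests (kept short so tests stay fast).
make_test_cohort <- function(n_subjects = 1, speeds = c(0.4, 1.0, 1.6),
                             duration = 15, noise_sd = 0, seed = 42) {
  gen_cohort(cohort_spec(n_subjects = n_subjects, speeds = speeds,
                         trial_duration = duration, sample_rate = 100,
                         noise_sd = noise_sd, seed = seed))
}
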