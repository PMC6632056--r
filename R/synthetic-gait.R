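# Speed-dependent anchors for the simulated cohort: peak push-off power,
# valley-to-peak power range, and peak occurrence (% of gait cycle) at the
# five treadmill speeds, linearly interpolated in between. Peaks grow and
# arrive earlier in the cycle as speed increases.
.gait_anchors <- list(
  speed      = c(0.4, 0.7, 1.0, 1.3, 1.6),
  peak_power = c(0.34, 0.91, 1.71, 2.52, 3.04),
  power_range = c(0.67, 1.55, 2.55, 3.52, 3.97),
  peak_occurrence = c(60.7, 60.3, 58.0, 56.6, 54.8)
)

# Fixed seed for the cohort-level base IMU waveforms. The base Fourier
# coefficients are a property of the simulator (the shared anatomy of the
# signal-to-power mapping); subjects perturb them (see make_profile_params).
.base_waveform_seed <- 8191L
.n_harmonics <- 6L
.subject_amp_sdlog <- 0.1      # log-normal sd of the subject power scale
.subject_coef_sdlog <- 0.08    # log-normal sd of per-subject harmonic amplitudes
.subject_phase_sd <- 0.1       # sd (rad) of per-subject harmonic phase shifts

# Each channel is dominated by the stride fundamental with a channel-specific
# phase lag spread around the circle (as foot/shank kinematics are), plus
# weaker random higher harmonics. The quadrature structure of the fundamental
# embeds gait phase injectively across the 12 channels, so phase remains
# decodable for subjects whose higher-harmonic content differs.
base_waveform_coefs <- function() {
  with_seed(.base_waveform_seed, {
    n_ch <- length(imu_channel_names())
    amp <- matrix(stats::runif(n_ch * .n_harmonics, 0.2, 0.6), n_ch) /
      matrix(seq_len(.n_harmonics), n_ch, .n_harmonics, byrow = TRUE)
    phase <- matrix(stats::runif(n_ch * .n_harmonics, 0, 2 * pi), n_ch)
    amp[, 1] <- 1
    phase[, 1] <- 2 * pi * (seq_len(n_ch) - 1) / n_ch
    list(amp = amp, phase = phase)
  })
}

interp_anchor <- function(speed, what) {
  stats::approx(.gait_anchors$speed, .gait_anchors[[what]], xout = speed,
                rule = 2)$y
}

#' Gait profile parameters for one subject at one speed
#'
#' Builds the parameter set that drives the synthetic gait generator. Peak
#' power, valley-to-peak power range and peak occurrence are linear
#' interpolations of the package's speed-anchored normative values, scaled by
#' a subject-level amplitude factor (drawn log-normally, sd(log) = 0.1, from
#' `subject_seed` unless given explicitly). The valley power is set so that
#' peak minus valley equals the interpolated power range. Each subject also
#' receives seeded perturbations of the base IMU waveform coefficients,
#' emulating individual signal morphology.
#'
#' @param speed walking speed in m/s, within \[0.3, 2.0\].
#' @param subject_seed integer seed identifying the subject; determines the
#'   subject scale and waveform perturbations reproducibly.
#' @param subject_scale optional explicit amplitude factor (overrides the
#'   seeded draw; `1` gives the normative profile exactly).
#' @param noise_sd sd of the Gaussian noise added to each IMU channel.
#' @param stance_fraction fraction of the cycle spent in stance (default 0.6).
#' @param cycle_duration cycle duration in s; default decreases linearly from
#'   1.4 s at 0.4 m/s to 1.0 s at 1.6 m/s.
#' @return object of class `gait_profile`.
#' @export
make_profile_params <- function(speed, subject_seed = NULL,
                                subject_scale = NULL, noise_sd = 0.1,
                                stance_fraction = 0.6, cycle_duration = NULL) {
  if (speed < 0.3 || speed > 2.0) {
    stop("`speed` must lie within [0.3, 2.0] m/s")
  }
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stop("`stance_fraction` must lie in (0, 1)")
  }
  base <- base_waveform_coefs()
  if (is.null(subject_seed)) {
    if (is.null(subject_scale)) subject_scale <- 1
    coef_amp <- base$amp
    coef_phase <- base$phase
  } else {
    drawn <- with_seed(subject_seed, {
      list(
        scale = stats::rlnorm(1, 0, .subject_amp_sdlog),
        amp_jitter = matrix(
          stats::rlnorm(length(base$amp), 0, .subject_coef_sdlog),
          nrow(base$amp)),
        phase_jitter = matrix(
          stats::rnorm(length(base$phase), 0, .subject_phase_sd),
          nrow(base$phase))
      )
    })
    if (is.null(subject_scale)) subject_scale <- drawn$scale
    coef_amp <- base$amp * drawn$amp_jitter
    coef_phase <- base$phase + drawn$phase_jitter
  }
  if (is.null(cycle_duration)) {
    cycle_duration <- 1.4 - (speed - 0.4) / 3
  }
  peak <- interp_anchor(speed, "peak_power") * subject_scale
  range_ <- interp_anchor(speed, "power_range") * subject_scale
  params <- structure(list(
    speed = speed,
    cycle_duration = cycle_duration,
    stance_fraction = stance_fraction,
    peak_power = peak,
    peak_occurrence = interp_anchor(speed, "peak_occurrence"),
    valley_power = peak - range_,
    subject_scale = subject_scale,
    noise_sd = noise_sd,
    channel_gain = interp_anchor(speed, "power_range") / 2.55,
    coef_amp = coef_amp,
    coef_phase = coef_phase,
    subject_seed = subject_seed
  ), class = "gait_profile")
  stopifnot(params$peak_power > 0, params$valley_power <= 0,
            params$peak_occurrence > 0, params$peak_occurrence < 100)
  params
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(paste0("Gait profile: %.2g m/s, cycle %.3g s, peak %.3g w/kg ",
                     "at %.3g%% of cycle, valley %.3g w/kg, scale %.3g\n"),
              x$speed, x$cycle_duration, x$peak_power, x$peak_occurrence,
              x$valley_power, x$subject_scale))
  invisible(x)
}

#' Generate one cycle of the ankle power template
#'
#' The single-cycle template is a positive Gaussian burst centred at the peak
#' occurrence (the push-off burst) plus a negative Gaussian dip centred at
#' mid-stance (eccentric absorption), with power returning to ~0 in late
#' swing. The maximum equals `peak_power` and its position equals
#' `peak_occurrence` up to the (negligible) overlap of the two lobes.
#'
#' @param params a [make_profile_params()] object.
#' @param n_samples number of samples in the cycle (>= 20).
#' @return numeric power series in w/kg of length `n_samples`.
#' @export
gen_power_cycle <- function(params, n_samples) {
  if (n_samples < 20) stop("`n_samples` must be >= 20")
  phase <- (seq_len(n_samples) - 1) / n_samples
  burst_centre <- params$peak_occurrence / 100
  dip_centre <- params$stance_fraction / 2
  params$peak_power * exp(-0.5 * ((phase - burst_centre) / 0.05)^2) +
    params$valley_power * exp(-0.5 * ((phase - dip_centre) / 0.07)^2)
}

#' Cohort specification for the synthetic study
#'
#' Defaults reproduce the study layout: nine subjects, five treadmill speeds
#' from 0.4 to 1.6 m/s, one-minute trials sampled at 100 Hz.
#'
#' @param n_subjects number of subjects (default 9).
#' @param speeds walking speeds in m/s.
#' @param trial_duration trial length in seconds (default 60).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param noise_sd sd of the additive Gaussian noise on each IMU channel
#'   (default 0.1, roughly 10% of the unit-scale channel amplitude).
#' @param seed integer master seed; the same seed yields a bit-identical
#'   cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 9,
                        speeds = c(0.4, 0.7, 1.0, 1.3, 1.6),
                        trial_duration = 60, sample_rate = 100,
                        noise_sd = 0.1, seed = 1) {
  stopifnot(n_subjects >= 1, length(speeds) >= 1, trial_duration > 0,
            sample_rate > 0)
  structure(list(n_subjects = n_subjects, speeds = speeds,
                 trial_duration = trial_duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one synthetic gait trial
#'
#' Concatenates gait cycles (durations jittered uniformly by up to ±3% per
#' cycle) up to the trial duration. The vertical GRF follows a double-bump
#' stance curve, strictly positive throughout stance and exactly zero in
#' swing. Each IMU channel is a band-limited periodic function of gait phase
#' (six seeded Fourier harmonics, amplitude scaled with speed) plus Gaussian
#' noise, so gait phase — and hence power — is recoverable from windowed
#' channel features. The reference power column is the cycle template of
#' [gen_power_cycle()].
#'
#' @param params a [make_profile_params()] object.
#' @param spec a [cohort_spec()] (its `trial_duration` and `sample_rate` are
#'   used).
#' @param seed integer seed for cycle jitter and channel noise.
#' @param subject_id subject label stored in the trial.
#' @return a [gait_trial()] with attributes `cycle_starts` (1-based start
#'   index of every constructed cycle) and `n_complete_cycles`.
#' @export
gen_trial <- function(params, spec, seed = 1, subject_id = "S1") {
  stopifnot(inherits(params, "gait_profile"), inherits(spec, "cohort_spec"))
  fs <- spec$sample_rate
  n_total <- round(spec$trial_duration * fs)
  with_seed(seed, {
    starts <- integer(0)
    phase <- numeric(0)
    grf <- numeric(0)
    power <- numeric(0)
    pos <- 1L
    while (pos <= n_total) {
      dur <- params$cycle_duration * (1 + stats::runif(1, -0.03, 0.03))
      n_k <- max(20L, as.integer(round(dur * fs)))
      starts <- c(starts, pos)
      ph_k <- (seq_len(n_k) - 1) / n_k
      n_st <- sum(ph_k < params$stance_fraction)
      s <- (seq_len(n_st) - 0.5) / n_st
      grf_k <- c(700 * (exp(-0.5 * ((s - 0.25) / 0.12)^2) +
                        exp(-0.5 * ((s - 0.75) / 0.12)^2)),
                 rep(0, n_k - n_st))
      phase <- c(phase, ph_k)
      grf <- c(grf, grf_k)
      power <- c(power, gen_power_cycle(params, n_k))
      pos <- pos + n_k
    }
    n_complete <- sum(c(starts[-1], pos) <= n_total + 1L)
    keep <- seq_len(n_total)
    data <- data.frame(time = (keep - 1) / fs)
    h_idx <- seq_len(.n_harmonics)
    for (ch in seq_along(imu_channel_names())) {
      clean <- rep(0, n_total)
      for (h in h_idx) {
        clean <- clean + params$coef_amp[ch, h] *
          cos(2 * pi * h * phase[keep] + params$coef_phase[ch, h])
      }
      noise <- if (params$noise_sd > 0) {
        stats::rnorm(n_total, 0, params$noise_sd)
      } else 0
      data[[imu_channel_names()[ch]]] <- params$channel_gain * clean + noise
    }
    data$grf <- grf[keep]
    data$power <- power[keep]
    trial <- gait_trial(subject_id, params$speed, fs, data)
    attr(trial, "cycle_starts") <- starts
    attr(trial, "n_complete_cycles") <- n_complete
    attr(trial, "profile") <- params
    trial
  })
}

#' Generate a full synthetic cohort
#'
#' One trial per subject and speed, with subject identity (amplitude scale
#' and waveform perturbations) held fixed across speeds. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `gait_cohort`: a list of [gait_trial()]s with the
#'   spec attached as an attribute.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- spec$n_subjects
  n_spd <- length(spec$speeds)
  seeds <- derive_seeds(spec$seed, n_sub * (n_spd + 1))
  subject_seeds <- seeds[seq_len(n_sub)]
  trial_seeds <- matrix(seeds[-seq_len(n_sub)], nrow = n_sub)
  trials <- vector("list", n_sub * n_spd)
  k <- 0L
  for (i in seq_len(n_sub)) {
    for (j in seq_len(n_spd)) {
      params <- make_profile_params(spec$speeds[j],
                                    subject_seed = subject_seeds[i],
                                    noise_sd = spec$noise_sd)
      k <- k + 1L
      trials[[k]] <- gen_trial(params, spec, seed = trial_seeds[i, j],
                               subject_id = sprintf("S%d", i))
    }
  }
  structure(trials, class = "gait_cohort", spec = spec)
}

#' @export
print.gait_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic gait cohort: %d trials (%d subjects x %d speeds), %g s at %g Hz\n",
              length(x), spec$n_subjects, length(spec$speeds),
              spec$trial_duration, spec$sample_rate))
  invisible(x)
}

#' Subject identifiers of a cohort
#' @param cohort a `gait_cohort`.
#' @return character vector of unique subject ids, in order.
#' @export
cohort_subjects <- function(cohort) {
  unique(vapply(cohort, function(tr) tr$subject_id, character(1)))
}
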