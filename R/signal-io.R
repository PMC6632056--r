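#' Names of the twelve IMU channels
#'
#' Three accelerometer axes (m/s^2) and three gyroscope axes (rad/s) for each
#' of the foot- and shank-mounted sensors, in the fixed column order used
#' throughout the package.
#'
#' @return character vector of length 12.
#' @export
imu_channel_names <- function() {
  as.vector(outer(
    c("x", "y", "z"),
    c("acc_foot", "gyr_foot", "acc_shank", "gyr_shank"),
    function(ax, ch) paste(ch, ax, sep = "_")
  ))
}

#' Construct a gait trial
#'
#' A trial is one subject-speed recording on a uniform timebase: twelve IMU
#' channels, vertical ground reaction force, and (optionally) reference
#' sagittal ankle joint power normalised by body mass.
#'
#' @param subject_id subject label.
#' @param speed treadmill speed in m/s.
#' @param sample_rate sampling rate in Hz.
#' @param data data.frame with columns `time`, the twelve channels of
#'   [imu_channel_names()], `grf` (N) and optionally `power` (w/kg).
#' @return object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, speed, sample_rate, data) {
  trial <- structure(
    list(subject_id = as.character(subject_id), speed = as.numeric(speed),
         sample_rate = as.numeric(sample_rate), data = data),
    class = "gait_trial"
  )
  validate_trial(trial)
  trial
}

validate_trial <- function(trial) {
  data <- trial$data
  required <- c("time", imu_channel_names(), "grf")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("trial format error: missing column '%s'", missing[[1L]]))
  }
  dt <- diff(data$time)
  step <- 1 / trial$sample_rate
  bad <- which(abs(dt - step) > step * 1e-6)
  if (length(bad) > 0L) {
    stop(sprintf("trial format error: non-uniform timebase in column 'time' at row %d",
                 bad[[1L]] + 1L))
  }
  neg <- which(data$grf < 0)
  if (length(neg) > 0L) {
    stop(sprintf("trial format error: negative value in column 'grf' at row %d",
                 neg[[1L]]))
  }
  invisible(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial: subject %s, %.2g m/s, %g Hz, %d samples (%.1f s)%s\n",
              x$subject_id, x$speed, x$sample_rate, nrow(x$data),
              nrow(x$data) / x$sample_rate,
              if ("power" %in% names(x$data)) ", with reference power" else ""))
  invisible(x)
}

#' Extract a contiguous slice of a trial
#'
#' Used by the evaluation protocols to split trials into training, calibration
#' and testing segments. The time column is kept (not re-zeroed) so sample
#' indices stay interpretable.
#'
#' @param trial a [gait_trial()].
#' @param from,to first and last sample (1-based, inclusive).
#' @return a `gait_trial` over the requested span.
#' @export
trial_slice <- function(trial, from, to) {
  stopifnot(from >= 1, to <= nrow(trial$data), from <= to)
  out <- trial
  out$data <- trial$data[from:to, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "offset") <- from - 1L
  out
}

#' Write a trial to a delimited text file
#'
#' The format is tab-separated values preceded by `#`-prefixed metadata lines
#' (`subject_id`, `speed`, `sample_rate`), with a header row naming every
#' column. Values are written with 17 significant digits so that a
#' write-then-read round trip reproduces every double exactly.
#'
#' @param trial a [gait_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  data <- trial$data
  meta <- c(
    sprintf("# subject_id: %s", trial$subject_id),
    sprintf("# speed: %.17g", trial$speed),
    sprintf("# sample_rate: %.17g", trial$sample_rate)
  )
  cols <- vapply(data, function(col) sprintf("%.17g", as.numeric(col)),
                 character(nrow(data)))
  if (nrow(data) == 1L) cols <- matrix(cols, nrow = 1L)
  lines <- c(meta, paste(names(data), collapse = "\t"),
             apply(cols, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial from a delimited text file
#'
#' Parses the format written by [write_trial()] and validates it: all
#' mandatory columns present, a uniform timebase, and non-negative ground
#' reaction force. Unknown extra columns are preserved.
#'
#' @param path input file path.
#' @return a [gait_trial()].
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  if (length(meta_idx) > 0 && !identical(meta_idx, seq_along(meta_idx))) {
    stop("trial format error: metadata lines must precede the data")
  }
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(m) != 1L) {
      stop(sprintf("trial format error: missing metadata line '%s'", key))
    }
    sub(sprintf("^#\\s*%s:\\s*", key), "", m)
  }
  data <- utils::read.table(
    text = lines[-meta_idx], header = TRUE, sep = "\t",
    colClasses = "numeric", check.names = FALSE
  )
  gait_trial(
    subject_id = get_meta("subject_id"),
    speed = as.numeric(get_meta("speed")),
    sample_rate = as.numeric(get_meta("sample_rate")),
    data = data
  )
}

#' Segment gait cycles from the vertical ground reaction force
#'
#' A gait cycle starts wherever the GRF rises above `threshold` (sample i
#' with `grf[i] > threshold` and `grf[i-1] <= threshold`) and the force then
#' stays above the threshold for at least `min_stance` samples — a debounce
#' against chatter around the threshold in noisy recordings. Cycle k spans
#' `[start_k, start_{k+1})` (1-based, half-open); the trailing partial cycle
#' is discarded.
#'
#' @param grf numeric GRF series in newtons.
#' @param threshold detection threshold in newtons (default 0).
#' @param min_stance minimum supra-threshold run length in samples
#'   (default 10, i.e. 100 ms at 100 Hz).
#' @return data.frame of class `gait_cycles` with columns `start`, `end`;
#'   zero rows when fewer than two qualifying onsets exist.
#' @export
segment_gait_cycles <- function(grf, threshold = 0, min_stance = 10) {
  if (any(!is.finite(grf))) stop("`grf` must be finite")
  if (threshold < 0) stop("`threshold` must be >= 0")
  if (min_stance < 1) stop("`min_stance` must be >= 1")
  above <- grf > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_stance & starts > 1L
  onsets <- starts[keep]
  if (length(onsets) < 2L) {
    cycles <- data.frame(start = integer(0), end = integer(0))
  } else {
    cycles <- data.frame(start = onsets[-length(onsets)], end = onsets[-1L])
  }
  class(cycles) <- c("gait_cycles", "data.frame")
  cycles
}
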