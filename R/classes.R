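# Core data containers. Plain S3 lists, in the style of classic
# time-series/statistics packages: cheap constructors that validate their
# invariants, plus print methods.

#' Construct an RR-interval series (tachogram)
#'
#' @param intervals Numeric vector of beat-to-beat intervals in
#'   milliseconds, all positive.
#' @param beat_times Optional numeric vector of the time (seconds) of the
#'   beat that *closes* each interval; strictly increasing. Defaults to
#'   the cumulative sum of the intervals.
#' @param normal Logical vector flagging each interval as a normal
#'   (sinus) interval; defaults to all `TRUE`. Flags are set by
#'   [nn_filter()] and honoured by every downstream metric.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, beat_times = NULL, normal = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stopf("`intervals` must be non-empty")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stopf("all RR intervals must be finite and positive (ms)")
  if (is.null(beat_times)) beat_times <- cumsum(intervals) / 1000
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) != length(intervals))
    stopf("`beat_times` must have one entry per interval")
  if (any(diff(beat_times) <= 0))
    stopf("`beat_times` must be strictly increasing")
  if (is.null(normal)) normal <- rep(TRUE, length(intervals))
  if (length(normal) != length(intervals))
    stopf("`normal` must have one flag per interval")
  structure(list(intervals = intervals, beat_times = beat_times,
                 normal = as.logical(normal)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("RR series: %d intervals, span %.1f s, mean %.1f ms, %d flagged non-normal\n",
              n, diff(range(x$beat_times)) + x$intervals[1] / 1000,
              mean(x$intervals), sum(!x$normal)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Construct a uniformly sampled ECG record
#'
#' @param samples Numeric voltage trace in millivolts.
#' @param fs Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, start_time = 0) {
  check_number(fs, "fs", lower = 1e-9)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stopf("ECG samples must be finite")
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Construct an R-peak annotation list
#'
#' @param times Strictly increasing peak times in seconds.
#' @param amplitudes Peak amplitudes in millivolts (optional).
#' @return An object of class `r_peaks`.
#' @export
r_peaks <- function(times, amplitudes = NULL) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stopf("peak times must be strictly increasing")
  structure(list(times = times,
                 amplitudes = if (is.null(amplitudes)) rep(NA_real_, length(times))
                              else as.numeric(amplitudes)),
            class = "r_peaks")
}

#' @export
print.r_peaks <- function(x, ...) {
  cat(sprintf("R peaks: %d detections over %.1f s\n", length(x$times),
              if (length(x$times) > 1) diff(range(x$times)) else 0))
  invisible(x)
}

#' Construct a uniformly resampled interval signal
#'
#' The output of [berger_resample()]: the RR interval signal (ms) on a
#' fixed grid, conventionally 10 Hz, ready for spectral analysis.
#'
#' @param values Interval signal in milliseconds.
#' @param fs_out Grid rate in Hz (default 10).
#' @param t0 Time of the first grid sample in seconds.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, fs_out = 10, t0 = 0) {
  check_number(fs_out, "fs_out", lower = 1e-9)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stopf("interval signal must be finite")
  structure(list(values = values, fs_out = fs_out, t0 = t0),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("Uniform interval signal: %d samples @ %g Hz, mean %.1f ms\n",
              length(x$values), x$fs_out, mean(x$values)))
  invisible(x)
}
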