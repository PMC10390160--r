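# Pan-Tompkins QRS detection rescaled to murine timing, tachogram
# construction, ectopy flagging and Berger resampling.

#' Detector parameters with murine defaults
#'
#' The classic Pan-Tompkins constants were designed for human QRS
#' complexes; murine QRS complexes are ~10 ms wide and heart rates reach
#' 600+ bpm, so the defaults here move the band-pass up to 10-100 Hz,
#' shrink the moving-integration window to 15 ms and the refractory
#' period to 50 ms.
#'
#' @param bandpass_low,bandpass_high Band-pass edges in Hz
#'   (0 < low < high < fs/2).
#' @param integration_window Moving-window integration length in ms.
#' @param refractory Minimum inter-beat spacing in ms.
#' @param searchback_factor Trigger a half-threshold searchback when the
#'   gap since the last beat exceeds this multiple of the running RR
#'   average.
#' @param update_gain Learning rate of the running signal/noise peak
#'   estimates (classic value 1/8).
#' @param polarity `"auto"` picks the dominant R-wave sign per record;
#'   `"positive"` assumes upright R waves; `"absolute"` refines on the
#'   rectified trace (fully polarity-agnostic).
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(bandpass_low = 10, bandpass_high = 100,
                            integration_window = 15, refractory = 50,
                            searchback_factor = 1.66, update_gain = 0.125,
                            polarity = c("auto", "positive", "absolute")) {
  check_number(bandpass_low, "bandpass_low", lower = 1e-9)
  check_number(bandpass_high, "bandpass_high", lower = bandpass_low + 1e-9)
  check_number(integration_window, "integration_window", lower = 1e-9)
  check_number(refractory, "refractory", lower = 1e-9)
  check_number(searchback_factor, "searchback_factor", lower = 1)
  check_number(update_gain, "update_gain", lower = 1e-6, upper = 1)
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 integration_window = integration_window,
                 refractory = refractory,
                 searchback_factor = searchback_factor,
                 update_gain = update_gain,
                 polarity = match.arg(polarity)),
            class = "detector_params")
}

# local maxima of x separated by at least min_sep samples
local_maxima <- function(x, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) < 2) return(cand)
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
    else if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
  }
  keep
}

#' Detect R peaks with a Pan-Tompkins detector
#'
#' Classic stage sequence: zero-phase Butterworth band-pass, five-point
#' derivative, squaring, moving-window integration, then dual adaptive
#' thresholding of the integrated signal with running signal/noise peak
#' estimates (new = gain*peak + (1-gain)*old), refractory blanking, and a
#' half-threshold searchback whenever the gap since the last accepted
#' beat exceeds `searchback_factor` times the running RR average. The
#' derivative and integration stages are applied with centered kernels
#' and the band-pass forward-backward, so the integrated fiducial carries
#' no group delay; each fiducial is then refined to the local extremum of
#' the raw trace within +/- one integration window.
#'
#' @param ecg An [ecg_record()] (at least 2 s of signal).
#' @param params A [detector_params()].
#' @return An [r_peaks()] object (times in seconds, amplitudes in mV).
#'   A flat (constant) trace yields zero peaks with a warning; fewer than
#'   two detections on a non-flat trace is an error.
#' @export
pan_tompkins_detect <- function(ecg, params = detector_params()) {
  if (!inherits(ecg, "ecg_record")) stopf("`ecg` must be an ecg_record")
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) < 2 * fs) stopf("need at least 2 s of signal for detection")
  if (params$bandpass_high >= fs / 2)
    stopf("bandpass_high must be below the Nyquist rate fs/2")
  if (stats::sd(x) == 0) {
    warnf("constant signal: no beats detected")
    return(structure(list(times = numeric(0), amplitudes = numeric(0)),
                     class = "r_peaks"))
  }

  bf <- signal::butter(2, c(params$bandpass_low, params$bandpass_high) / (fs / 2),
                       type = "pass")
  xf <- signal::filtfilt(bf, x)

  # centered five-point derivative, squaring, centered moving integration
  dkern <- c(2, 1, 0, -1, -2) / 8 * fs / 4
  xd <- stats::filter(xf, dkern, sides = 2)
  xd[is.na(xd)] <- 0
  xs <- as.numeric(xd)^2
  wlen <- max(3L, round(params$integration_window / 1000 * fs))
  if (wlen %% 2 == 0) wlen <- wlen + 1L
  xi <- stats::filter(xs, rep(1 / wlen, wlen), sides = 2)
  xi[is.na(xi)] <- 0
  xi <- as.numeric(xi)

  refr <- round(params$refractory / 1000 * fs)
  cand <- local_maxima(xi, min_sep = max(3L, refr %/% 2L))
  if (length(cand) == 0) {
    warnf("no candidate peaks found")
    return(structure(list(times = numeric(0), amplitudes = numeric(0)),
                     class = "r_peaks"))
  }

  # threshold initialization from the first 2 s
  init <- xi[seq_len(min(length(xi), round(2 * fs)))]
  spki <- max(init)
  npki <- mean(init) * 0.5
  g <- params$update_gain
  thr <- function() npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_avg <- NA_real_
  noise_cand <- integer(0)
  for (i in cand) {
    gap_ok <- length(qrs) == 0 || (i - qrs[length(qrs)]) > refr
    if (xi[i] > thr() && gap_ok) {
      qrs <- c(qrs, i)
      spki <- g * xi[i] + (1 - g) * spki
      noise_cand <- integer(0)
    } else {
      npki <- g * xi[i] + (1 - g) * npki
      if (gap_ok) noise_cand <- c(noise_cand, i)
    }
    if (length(qrs) >= 2) {
      rrs <- diff(utils::tail(qrs, 9))
      rr_avg <- mean(rrs)
      # searchback: gap since last beat too long -> re-examine skipped
      # candidates at half threshold (halved learning on acceptance)
      if ((i - qrs[length(qrs)]) > params$searchback_factor * rr_avg &&
          length(noise_cand) > 0) {
        sb <- noise_cand[noise_cand > qrs[length(qrs)] + refr]
        if (length(sb) > 0) {
          best <- sb[which.max(xi[sb])]
          if (xi[best] > 0.5 * thr()) {
            qrs <- sort(c(qrs, best))
            spki <- (g / 2) * xi[best] + (1 - g / 2) * spki
            noise_cand <- integer(0)
          }
        }
      }
    }
  }
  if (length(qrs) < 2) stopf("too few beats detected (%d)", length(qrs))

  # refine each fiducial on the raw trace (local baseline removed)
  half <- max(1L, round(params$integration_window / 1000 * fs))
  n <- length(x)
  sign_mode <- params$polarity
  refined <- vapply(qrs, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    seg <- x[lo:hi] - stats::median(x[lo:hi])
    j <- switch(sign_mode,
      positive = which.max(seg),
      absolute = which.max(abs(seg)),
      auto = if (max(seg) >= -min(seg)) which.max(seg) else which.min(seg))
    as.integer(lo + j - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) > refr)
    refined <- refined[keep]
  }
  r_peaks(times = ecg$start_time + (refined - 1L) / fs,
          amplitudes = x[refined])
}

#' Build the RR tachogram from detected peaks
#'
#' @param peaks An [r_peaks()] object with at least 3 peaks.
#' @return An [rr_series()]; `intervals[i]` is the time from peak i to
#'   peak i+1 in ms, timestamped by the closing peak; all flags normal.
#' @export
rr_from_peaks <- function(peaks) {
  if (!inherits(peaks, "r_peaks")) stopf("`peaks` must be an r_peaks object")
  if (length(peaks$times) < 3) stopf("need at least 3 peaks to form a tachogram")
  if (any(diff(peaks$times) <= 0)) stopf("peak times must be strictly increasing")
  rr_series(diff(peaks$times) * 1000, beat_times = peaks$times[-1])
}

#' Flag non-normal (ectopic-like) intervals
#'
#' An interval is flagged non-normal when it deviates from the local
#' running median by more than `deviation_limit` times that median.
#' Flagged intervals are excluded from all downstream metrics. This is a
#' generic artifact screen; it defaults to off for synthetic data
#' (`deviation_limit` must be chosen by the caller).
#'
#' @param rr An [rr_series()].
#' @param deviation_limit Fractional deviation threshold, in (0, 1).
#' @param window Odd window length (beats, >= 3) for the running median.
#' @return The `rr_series` with updated `normal` flags.
#' @export
nn_filter <- function(rr, deviation_limit = 0.2, window = 11) {
  if (!inherits(rr, "rr_series")) stopf("`rr` must be an rr_series")
  if (!is.numeric(deviation_limit) || deviation_limit <= 0 || deviation_limit >= 1)
    stopf("`deviation_limit` must lie strictly between 0 and 1")
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) stopf("`window` must be odd and >= 3")
  n <- length(rr$intervals)
  half <- window %/% 2
  med <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    stats::median(rr$intervals[setdiff(idx, i)])
  }, numeric(1))
  rr$normal <- abs(rr$intervals - med) <= deviation_limit * med
  rr
}

#' Resample a tachogram to a uniform grid by Berger's method
#'
#' For each output sample a window of width `2/fs_out` centered on the
#' sample counts the fractional number of beat intervals it overlaps;
#' the local rate is `fs_out/2` times that count and the stored value is
#' the equivalent interval `1000/rate` in ms. Output samples whose
#' window extends beyond the recorded beat train are dropped rather than
#' padded. Intervals flagged non-normal are merged with their successor
#' (the beat closing the flagged interval is removed from the train).
#'
#' @param rr An [rr_series()] with at least 3 normal intervals spanning
#'   at least `2/fs_out` seconds.
#' @param fs_out Output grid rate in Hz (default 10).
#' @return A [uniform_series()] (values in ms).
#' @export
berger_resample <- function(rr, fs_out = 10) {
  if (!inherits(rr, "rr_series")) stopf("`rr` must be an rr_series")
  check_number(fs_out, "fs_out", lower = 1e-9)
  if (sum(rr$normal) < 3) stopf("need at least 3 normal intervals")
  beats <- c(rr$beat_times[1] - rr$intervals[1] / 1000, rr$beat_times)
  # merge flagged intervals with their successor
  if (any(!rr$normal)) {
    drop <- which(!rr$normal)
    drop <- drop[drop < length(rr$intervals)]  # keep the final beat
    if (length(drop) > 0) beats <- beats[-(drop + 1L)]
  }
  span <- beats[length(beats)] - beats[1]
  if (span < 2 / fs_out) stopf("recording span too short for fs_out = %g", fs_out)

  # grid anchored to the beat train, so a global time shift of the
  # beats shifts the grid with them (shift-invariant values); samples
  # whose window would leave the record are dropped, not padded
  halfw <- 1 / fs_out
  t_out <- seq(beats[1] + halfw, beats[length(beats)] - halfw,
               by = 1 / fs_out)
  if (length(t_out) < 2) stopf("recording span too short for fs_out = %g", fs_out)

  ints_lo <- beats[-length(beats)]
  ints_hi <- beats[-1]
  ints_len <- ints_hi - ints_lo
  counts <- vapply(t_out, function(tc) {
    lo <- tc - halfw; hi <- tc + halfw
    ov <- pmin(ints_hi, hi) - pmax(ints_lo, lo)
    sum(pmax(ov, 0) / ints_len)
  }, numeric(1))
  rate <- counts * fs_out / 2            # beats per second
  uniform_series(1000 / rate, fs_out = fs_out, t0 = t_out[1])
}
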