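# Frequency-domain HRV: Welch power spectral density of the uniform
# 10 Hz interval signal and murine band powers.

#' Welch power spectral density of a uniform interval signal
#'
#' Splits the signal into overlapping segments, removes each segment's
#' mean and linear trend, applies a Hann taper, and averages the
#' one-sided segment periodograms. The averaged density is then given a
#' variance-preserving normalization: it is rescaled so that its
#' integral equals the mean variance of the detrended (untapered)
#' segments, removing the taper's center-weighting so Parseval holds
#' for every input rather than only in expectation.
#'
#' @param series A [uniform_series()] (10 Hz by convention).
#' @param window Segment length in seconds (default 60).
#' @param overlap Fractional segment overlap in [0, 0.95] (default 0.5).
#' @return A list of class `hrv_spectrum` with `frequencies` (Hz, 0 to
#'   fs_out/2), `density` (ms^2/Hz), and method metadata.
#' @export
welch_psd <- function(series, window = 60, overlap = 0.5) {
  if (!inherits(series, "uniform_series")) stopf("`series` must be a uniform_series")
  fs <- series$fs_out
  x <- series$values
  span <- length(x) / fs
  check_number(window, "window", lower = 1e-9)
  if (overlap < 0 || overlap >= 0.95) stopf("`overlap` must be in [0, 0.95)")
  nper <- round(window * fs)
  if (length(x) < nper)
    stopf("series span (%.0f s) shorter than the window (%.0f s); use a shorter window",
          span, window)

  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann
  wnorm <- sum(w^2)
  nfreq <- nper %/% 2 + 1L
  tt <- seq_len(nper)

  acc <- numeric(nfreq)
  segvar <- 0
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), seg)       # mean + linear trend
    segvar <- segvar + mean(fit$residuals^2)
    seg <- fit$residuals * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    p <- (Mod(X)^2) / (fs * wnorm)
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]     # one-sided
    acc <- acc + p
  }
  density <- acc / length(starts)
  segvar <- segvar / length(starts)
  freqs <- (seq_len(nfreq) - 1L) * fs / nper
  raw_int <- sum((density[-1] + density[-nfreq]) / 2 * diff(freqs))
  if (raw_int > 0) density <- density * segvar / raw_int
  structure(list(frequencies = freqs,
                 density = density,
                 window = window, overlap = overlap, taper = "hann",
                 n_segments = length(starts), fs_out = fs),
            class = "hrv_spectrum")
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d bins to %.1f Hz (%d x %.0f s %s segments, %.0f%% overlap)\n",
              length(x$frequencies), max(x$frequencies), x$n_segments,
              x$window, x$taper, 100 * x$overlap))
  invisible(x)
}

#' Murine VLF/LF/HF band powers
#'
#' Integrates the spectrum trapezoidally over the murine bands
#' VLF [0, 0.15), LF [0.15, 1.5), HF [1.5, 5] Hz (each spectral
#' sub-interval is assigned to the band containing its midpoint, making
#' the bands a partition); the 0 Hz bin (the mean) is excluded. Total
#' power is the sum of the three bands and relative powers are expressed
#' in percent of it.
#'
#' @param spec An `hrv_spectrum` from [welch_psd()] covering 0-5 Hz.
#' @param edges Band edges in Hz: `c(vlf_hi, lf_hi, hf_hi)`.
#' @return A list of class `band_power_result` with absolute powers
#'   (ms^2), relative powers (%), `total_power` and `lf_hf`.
#' @export
band_powers <- function(spec, edges = c(0.15, 1.5, 5)) {
  if (!inherits(spec, "hrv_spectrum")) stopf("`spec` must be an hrv_spectrum")
  f <- spec$frequencies
  d <- spec$density
  if (max(f) < edges[3] - 1e-9)
    stopf("spectrum must cover 0-%g Hz", edges[3])
  d[f == 0] <- 0                              # exclude the mean
  mid <- (f[-1] + f[-length(f)]) / 2
  area <- (d[-1] + d[-length(d)]) / 2 * diff(f)
  vlf <- sum(area[mid < edges[1]])
  lf  <- sum(area[mid >= edges[1] & mid < edges[2]])
  hf  <- sum(area[mid >= edges[2] & mid <= edges[3]])
  total <- vlf + lf + hf
  if (total < 1e-12)
    stopf("total band power is zero; relative powers undefined")
  structure(list(vlf_abs = vlf, lf_abs = lf, hf_abs = hf,
                 total_power = total,
                 vlf_rel = 100 * vlf / total, lf_rel = 100 * lf / total,
                 hf_rel = 100 * hf / total,
                 lf_hf = lf / hf),
            class = "band_power_result")
}

#' @export
print.band_power_result <- function(x, ...) {
  cat(sprintf("Band powers: VLF %.3g (%.1f%%), LF %.3g (%.1f%%), HF %.3g (%.1f%%) ms^2; TP %.3g; LF/HF %.2f\n",
              x$vlf_abs, x$vlf_rel, x$lf_abs, x$lf_rel, x$hf_abs, x$hf_rel,
              x$total_power, x$lf_hf))
  invisible(x)
}

#' Spectral analysis of an RR series end to end
#'
#' Convenience wrapper: Berger-resamples the tachogram at `fs_out` and
#' returns both the Welch spectrum and the band powers.
#'
#' @param rr An [rr_series()].
#' @param fs_out Resampling rate in Hz (default 10).
#' @param window,overlap Passed to [welch_psd()].
#' @return A list with `spectrum` and `bands`.
#' @export
frequency_domain_metrics <- function(rr, fs_out = 10, window = 60, overlap = 0.5) {
  u <- berger_resample(rr, fs_out = fs_out)
  sp <- welch_psd(u, window = window, overlap = overlap)
  list(spectrum = sp, bands = band_powers(sp))
}
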