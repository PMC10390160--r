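# Time-domain HRV indices: SDNN, RMSSD, TINN, mean HR.
#
# All functions accept either an rr_series (whose non-normal flags are
# honoured) or a bare numeric vector of NN intervals in milliseconds.

#' Standard deviation of NN intervals (SDNN)
#'
#' Sample standard deviation (denominator N-1) of the normal
#' beat-to-beat intervals, in ms. The conventional short-term segment is
#' five minutes; see [window_rr()] for windowing.
#'
#' @param nn An [rr_series()] or numeric vector of NN intervals (ms).
#' @return SDNN in ms.
#' @export
sdnn <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 2) stopf("SDNN needs at least 2 normal intervals")
  stats::sd(x)
}

#' Root mean square of successive differences (RMSSD)
#'
#' Square root of the mean squared difference between adjacent normal
#' intervals, in ms. Differences are taken only between intervals that
#' are adjacent in the normal-flagged sequence.
#'
#' @inheritParams sdnn
#' @return RMSSD in ms.
#' @export
rmssd <- function(nn) {
  x <- nn_intervals(nn)
  d <- diff(x)
  if (length(d) < 2) stopf("RMSSD needs at least 2 successive differences")
  sqrt(mean(d^2))
}

#' Triangular interpolation of the NN histogram (TINN)
#'
#' Builds a histogram of the NN intervals at `bin_width` ms resolution,
#' fixes its peak (mode bin center X, count Y), and searches
#' exhaustively over bin-aligned baseline points N <= X <= M for the
#' triangle (zero outside [N, M], linear N -> (X, Y) -> M) minimizing the
#' integrated squared error against the histogram. Returns the baseline
#' width M - N in ms. Degenerate single-bin histograms return 0.
#'
#' The default 1 ms bin is much finer than the human-standard 1/128 s
#' because murine NN spread is only a few ms.
#'
#' @inheritParams sdnn
#' @param bin_width Histogram bin width in ms (default 1).
#' @return TINN in ms.
#' @export
tinn <- function(nn, bin_width = 1) {
  x <- nn_intervals(nn)
  if (length(x) < 20) stopf("TINN needs at least 20 normal intervals")
  check_number(bin_width, "bin_width", lower = 1e-9)

  b0 <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(b0, max(x) + bin_width, by = bin_width)
  counts <- as.numeric(table(cut(x, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  centers <- breaks[-length(breaks)] + bin_width / 2
  if (sum(counts > 0) == 1) return(0)

  # pad so the baseline can extend beyond the occupied support
  pad <- length(centers) + 2L
  centers <- c(seq(centers[1] - pad * bin_width, centers[1] - bin_width,
                   by = bin_width),
               centers,
               seq(centers[length(centers)] + bin_width,
                   centers[length(centers)] + pad * bin_width, by = bin_width))
  counts <- c(numeric(pad), counts, numeric(pad))

  peak <- which.max(counts)
  X <- centers[peak]; Y <- counts[peak]
  best <- c(err = Inf, N = X, M = X)
  idxN <- which(centers <= X)
  idxM <- which(centers >= X)
  for (iN in idxN) {
    N <- centers[iN]
    up <- if (X > N) pmax(0, pmin(1, (centers - N) / (X - N))) * Y else
      ifelse(centers == X, Y, 0)
    for (iM in idxM) {
      M <- centers[iM]
      down <- if (M > X) pmax(0, pmin(1, (M - centers) / (M - X))) * Y else
        ifelse(centers == X, Y, 0)
      tri <- ifelse(centers < N | centers > M, 0, pmin(up, down))
      err <- sum((counts - tri)^2)
      if (err < best["err"] - 1e-12) best <- c(err = err, N = N, M = M)
    }
  }
  unname(best["M"] - best["N"])
}

#' Mean heart rate from NN intervals
#'
#' Defined via the mean interval, `60000 / mean(NN)` bpm (not the mean of
#' instantaneous rates, which differs for variable series).
#'
#' @inheritParams sdnn
#' @return Mean HR in beats per minute.
#' @export
mean_hr <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 1) stopf("mean HR needs at least 1 normal interval")
  60000 / mean(x)
}

#' Cut an RR series into fixed-length analysis windows
#'
#' Helper honouring the conventional five-minute short-term segment:
#' splits the series at `segment` second boundaries of beat time and
#' returns complete windows only.
#'
#' @param rr An [rr_series()].
#' @param segment Window length in seconds (default 300).
#' @return A list of [rr_series()] windows.
#' @export
window_rr <- function(rr, segment = 300) {
  if (!inherits(rr, "rr_series")) stopf("`rr` must be an rr_series")
  check_number(segment, "segment", lower = 1)
  t0 <- rr$beat_times[1] - rr$intervals[1] / 1000
  rel <- rr$beat_times - t0
  idx <- floor((rel - 1e-12) / segment)
  full <- seq_len(max(0, floor(max(rel) / segment))) - 1L
  lapply(full, function(w) {
    sel <- idx == w
    rr_series(rr$intervals[sel], beat_times = rr$beat_times[sel],
              normal = rr$normal[sel])
  })
}

#' All time-domain indices at once
#'
#' @inheritParams sdnn
#' @param bin_width TINN histogram bin width in ms.
#' @return A list of class `time_domain_result` with fields `sdnn`,
#'   `rmssd`, `tinn`, `mean_hr`, `mean_nn`, `n_beats`, `segment_length`.
#' @export
time_domain_metrics <- function(nn, bin_width = 1) {
  x <- nn_intervals(nn)
  span <- if (inherits(nn, "rr_series"))
    diff(range(nn$beat_times)) + nn$intervals[1] / 1000 else sum(x) / 1000
  structure(list(
    sdnn = sdnn(x), rmssd = rmssd(x),
    tinn = if (length(x) >= 20) tinn(x, bin_width) else NA_real_,
    mean_hr = mean_hr(x), mean_nn = mean(x),
    n_beats = length(x), segment_length = span),
    class = "time_domain_result")
}

#' @export
print.time_domain_result <- function(x, ...) {
  cat(sprintf("Time domain (%d beats, %.0f s): SDNN %.2f ms, RMSSD %.2f ms, TINN %s ms, mean HR %.1f bpm\n",
              x$n_beats, x$segment_length, x$sdnn, x$rmssd,
              ifelse(is.na(x$tinn), "NA", sprintf("%.1f", x$tinn)), x$mean_hr))
  invisible(x)
}
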