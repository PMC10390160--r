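# Nonlinear HRV: detrended fluctuation analysis, Poincare plot
# descriptors, approximate and sample entropy.

#' Detrended fluctuation analysis of an NN series
#'
#' The series is integrated about its mean, y(k) = sum_{i<=k}(NN_i -
#' mean(NN)); for each box size n the integrated profile is split into
#' floor(N/n) non-overlapping boxes from the start (any tail discarded),
#' a least-squares line is fitted per box, and the fluctuation F(n) is
#' the root mean square of the detrended profile over the covered
#' length. The short- and long-range scaling exponents alpha1 and alpha2
#' are the least-squares slopes of log F(n) vs log n over the two fit
#' ranges (natural logs; the slope is base-invariant).
#'
#' The default ranges are the inclusive integer ranges 4..11 and 12..64,
#' following the convention of starting the short-range fit at 4 beats;
#' set `inclusive = FALSE` for the strict reading 5..10 / 13..63.
#'
#' Linear-detrend fluctuations carry a documented upward bias at small
#' box sizes: for an uncorrelated series the expected squared
#' fluctuation is sigma^2 (n^2 - 4)/(15 n) rather than proportional to
#' n, which inflates the short-range slope to ~0.62. By default F(n) is
#' divided by sqrt(1 - 4/n^2), the exact finite-box factor for
#' uncorrelated input, which restores alpha = 0.5 scaling for white
#' noise at every n and is negligible (< 0.01 in slope) over the
#' long-range fit; `small_box_correction = FALSE` gives the plain
#' estimator.
#'
#' @inheritParams sdnn
#' @param range1,range2 Box-size limits (beats) for alpha1 and alpha2.
#' @param inclusive Include the range endpoints (default TRUE).
#' @param small_box_correction Apply the finite-box bias correction
#'   (default TRUE).
#' @return A list of class `dfa_result` with `box_sizes`, `fluctuation`
#'   (ms), `alpha1`, `alpha2` and the fit ranges.
#' @export
dfa <- function(nn, range1 = c(4, 11), range2 = c(12, 64), inclusive = TRUE,
                small_box_correction = TRUE) {
  x <- nn_intervals(nn)
  nmax <- range2[2]
  if (length(x) < 2 * nmax)
    stopf("DFA needs at least %d normal intervals (2 boxes at n = %d)",
          2 * nmax, nmax)
  if (!inclusive) {
    range1 <- range1 + c(1, -1)
    range2 <- range2 + c(1, -1)
  }
  y <- cumsum(x - mean(x))
  N <- length(y)
  sizes <- seq(min(range1[1], 4), nmax)
  fluct <- vapply(sizes, function(n) {
    nbox <- N %/% n
    len <- nbox * n
    yy <- matrix(y[seq_len(len)], nrow = n)       # one box per column
    k <- seq_len(n)
    # closed-form least-squares line per box
    kc <- k - mean(k)
    slope <- colSums(yy * kc) / sum(kc^2)
    resid <- yy - outer(kc, slope) - rep(colMeans(yy), each = n)
    sqrt(mean(resid^2))
  }, numeric(1))
  if (small_box_correction) fluct <- fluct / sqrt(1 - 4 / sizes^2)

  fit_alpha <- function(rng) {
    sel <- sizes >= rng[1] & sizes <= rng[2]
    Fv <- fluct[sel]
    if (any(Fv <= 0)) stopf("degenerate fluctuation: F(n) = 0 inside the fit range")
    if (sum(sel) < 3) stopf("fewer than 3 box sizes in the fit range")
    unname(stats::coef(stats::lm(log(Fv) ~ log(sizes[sel])))[2])
  }
  structure(list(box_sizes = sizes, fluctuation = fluct,
                 alpha1 = fit_alpha(range1), alpha2 = fit_alpha(range2),
                 range1 = range1, range2 = range2),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: alpha1 = %.3f (n %d-%d), alpha2 = %.3f (n %d-%d)\n",
              x$alpha1, x$range1[1], x$range1[2],
              x$alpha2, x$range2[1], x$range2[2]))
  invisible(x)
}

#' Poincare plot descriptors SD1, SD2 and their ratio
#'
#' Pairs each normal interval with its successor, x = NN[1..K-1],
#' y = NN[2..K], and measures the dispersion of the cloud across and
#' along the line of identity: SD1 is the standard deviation of
#' (x - y)/sqrt(2) and SD2 of (x + y)/sqrt(2), both about their means
#' with the pair count K-1 as denominator. SD1 captures short-term
#' (vagal) variability, SD2 long-term; SD2/SD1 is the geometric
#' analogue of LF/HF.
#'
#' @inheritParams sdnn
#' @return A list of class `poincare_result` with `sd1`, `sd2` (ms),
#'   `ratio_sd2_sd1` (NA when SD1 = 0) and the ellipse `center`.
#' @export
poincare <- function(nn) {
  v <- nn_intervals(nn)
  if (length(v) < 3) stopf("Poincare analysis needs at least 3 normal intervals")
  x <- v[-length(v)]
  y <- v[-1]
  d1 <- (x - y) / sqrt(2)
  d2 <- (x + y) / sqrt(2)
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))   # denominator = pair count
  sd1 <- pop_sd(d1)
  sd2 <- pop_sd(d2)
  structure(list(sd1 = sd1, sd2 = sd2,
                 ratio_sd2_sd1 = if (sd1 > 0) sd2 / sd1 else NA_real_,
                 center = c(mean(x), mean(y))),
            class = "poincare_result")
}

#' @export
print.poincare_result <- function(x, ...) {
  cat(sprintf("Poincare: SD1 %.3f ms, SD2 %.3f ms, SD2/SD1 %s\n",
              x$sd1, x$sd2,
              ifelse(is.na(x$ratio_sd2_sd1), "undefined",
                     sprintf("%.2f", x$ratio_sd2_sd1))))
  invisible(x)
}

# Chebyshev-distance template match counts. Returns, for each of the
# n - m + 1 templates of length m, the number of templates within r
# (self-match included).
template_match_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m + 1L
  cnt <- matrix(TRUE, nt, nt)
  for (j in seq_len(m)) {
    seg <- x[j:(j + nt - 1L)]
    cnt <- cnt & (abs(outer(seg, seg, "-")) <= r)
  }
  rowSums(cnt)
}

#' Approximate entropy of an NN series
#'
#' ApEn(m, r) with the tolerance r expressed as a fraction of the sample
#' standard deviation (`r_frac`, conventionally 0.2, i.e. 20%), pattern
#' length m (conventionally 2), Chebyshev distance, self-matches
#' included: ApEn = Phi^m - Phi^(m+1) where Phi^m is the mean natural
#' log of the fraction of length-m templates within r of each template.
#' A constant series returns 0.
#'
#' @inheritParams sdnn
#' @param m Pattern length (default 2).
#' @param r_frac Tolerance as a fraction of the series SD (default 0.2).
#' @return A list of class `entropy_result` with `apen` (nats), `m`,
#'   `r` (ms), `n_used`.
#' @export
apen <- function(nn, m = 2, r_frac = 0.2) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < 50) stopf("ApEn needs at least 50 normal intervals")
  if (m >= n) stopf("pattern length m must be smaller than the series length")
  r <- r_frac * stats::sd(x)
  value <- if (r == 0) 0 else {
    phi <- function(mm) {
      cnt <- template_match_counts(x, mm, r)
      mean(log(cnt / (n - mm + 1L)))
    }
    phi(m) - phi(m + 1L)
  }
  structure(list(apen = value, m = m, r = r, r_frac = r_frac, n_used = n),
            class = "entropy_result")
}

#' Sample entropy of an NN series
#'
#' SampEn(m, r): with A the number of ordered pairs (i != j) of length
#' m+1 templates within Chebyshev distance r and B the same count for
#' length m (both over the first N - m template positions, excluding
#' self-matches), SampEn = -ln(A/B). When A = 0 the value is undefined
#' and reported as `NA` with the pair counts attached; a constant series
#' returns 0.
#'
#' @inheritParams apen
#' @return A list of class `entropy_result` with `sampen` (nats), `m`,
#'   `r` (ms), `n_used`, `A`, `B`.
#' @export
sampen <- function(nn, m = 2, r_frac = 0.2) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < 50) stopf("SampEn needs at least 50 normal intervals")
  if (m >= n) stopf("pattern length m must be smaller than the series length")
  r <- r_frac * stats::sd(x)
  if (r == 0) {
    return(structure(list(sampen = 0, m = m, r = r, r_frac = r_frac,
                          n_used = n, A = NA_real_, B = NA_real_),
                     class = "entropy_result"))
  }
  nt <- n - m                                   # common template count
  count_pairs <- function(mm) {
    cnt <- matrix(TRUE, nt, nt)
    for (j in seq_len(mm)) {
      seg <- x[j:(j + nt - 1L)]
      cnt <- cnt & (abs(outer(seg, seg, "-")) <= r)
    }
    sum(cnt) - nt                               # exclude self-matches
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  value <- if (B == 0 || A == 0) NA_real_ else -log(A / B)
  structure(list(sampen = value, m = m, r = r, r_frac = r_frac,
                 n_used = n, A = A, B = B),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  lab <- if (!is.null(x$apen)) c("ApEn", x$apen) else c("SampEn", x$sampen)
  cat(sprintf("%s(m=%d, r=%.3g ms, N=%d) = %s\n", lab[1], x$m, x$r, x$n_used,
              ifelse(is.na(as.numeric(lab[2])), "undefined",
                     sprintf("%.4f", as.numeric(lab[2])))))
  invisible(x)
}

#' All nonlinear indices at once
#'
#' @inheritParams sdnn
#' @param m,r_frac Entropy parameters.
#' @return A list with `dfa`, `poincare`, `apen`, `sampen` components
#'   (each `NULL` with an attached message when its precondition fails).
#' @export
nonlinear_metrics <- function(nn, m = 2, r_frac = 0.2) {
  list(dfa = dfa(nn), poincare = poincare(nn),
       apen = apen(nn, m, r_frac), sampen = sampen(nn, m, r_frac))
}
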