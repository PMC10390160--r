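# Independent oracles used across the suite. These are deliberately
# naive (loop-based, closed-form) re-derivations kept separate from the
# package's vectorized implementations.

# Match detected peak times against ground truth within a tolerance (s);
# greedy one-to-one matching in truth order.
match_peaks <- function(detected, truth, tol = 0.0025) {
  used <- logical(length(detected))
  tp <- 0L
  max_err <- 0
  for (tt in truth) {
    j <- which(!used & abs(detected - tt) <= tol)
    if (length(j) > 0) {
      j <- j[which.min(abs(detected[j] - tt))]
      used[j] <- TRUE
      tp <- tp + 1L
      max_err <- max(max_err, abs(detected[j] - tt))
    }
  }
  list(sensitivity = tp / length(truth), ppv = tp / length(detected),
       max_err = max_err)
}

cheb_dist <- function(x, i, j, m) {
  d <- 0
  for (k in 0:(m - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
  d
}

# Brute-force ApEn: O(N^2) explicit pair loops, self-matches included.
apen_bruteforce <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  if (r == 0) return(0)
  phi <- function(mm) {
    nt <- n - mm + 1L
    logc <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) if (cheb_dist(x, i, j, mm) <= r) cnt <- cnt + 1L
      logc[i] <- log(cnt / nt)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1L)
}

# Brute-force SampEn: ordered pairs i != j over the first n - m
# templates for both lengths.
sampen_bruteforce <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  if (r == 0) return(list(value = 0, A = NA, B = NA))
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    if (cheb_dist(x, i, j, m) <= r) B <- B + 1L
    if (cheb_dist(x, i, j, m + 1L) <= r) A <- A + 1L
  }
  list(value = if (A > 0 && B > 0) -log(A / B) else NA_real_, A = A, B = B)
}

# Naive DFA: per-box lm() fits, plain Eq.-style fluctuation (no
# small-box correction), natural-log slope fit.
dfa_bruteforce <- function(x, range1 = c(4, 11), range2 = c(12, 64)) {
  y <- cumsum(x - mean(x))
  N <- length(y)
  sizes <- 4:range2[2]
  Fv <- sapply(sizes, function(n) {
    nbox <- N %/% n
    res2 <- numeric(0)
    for (b in seq_len(nbox)) {
      idx <- ((b - 1) * n + 1):(b * n)
      fit <- stats::lm(y[idx] ~ idx)
      res2 <- c(res2, stats::resid(fit)^2)
    }
    sqrt(mean(res2))
  })
  slope <- function(rng) {
    sel <- sizes >= rng[1] & sizes <= rng[2]
    unname(stats::coef(stats::lm(log(Fv[sel]) ~ log(sizes[sel])))[2])
  }
  list(sizes = sizes, F = Fv, alpha1 = slope(range1), alpha2 = slope(range2))
}

# Exhaustive triangular-fit baseline width on a prebuilt histogram
# (counts at unit-spaced centers), searching a padded center grid.
tinn_oracle <- function(x, bin_width = 1) {
  b0 <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(b0, max(x) + bin_width, by = bin_width)
  counts <- as.numeric(table(cut(x, breaks, right = FALSE, include.lowest = TRUE)))
  centers <- breaks[-length(breaks)] + bin_width / 2
  pad <- length(centers) + 2L
  centers <- c(seq(min(centers) - pad * bin_width, min(centers) - bin_width, by = bin_width),
               centers,
               seq(max(centers) + bin_width, max(centers) + pad * bin_width, by = bin_width))
  counts <- c(numeric(pad), counts, numeric(pad))
  p <- which.max(counts); X <- centers[p]; Y <- counts[p]
  best_err <- Inf; best <- c(X, X)
  for (N in centers[centers <= X]) for (M in centers[centers >= X]) {
    tri <- numeric(length(centers))
    for (k in seq_along(centers)) {
      cc <- centers[k]
      if (cc < N || cc > M) next
      tri[k] <- if (cc <= X) { if (X > N) Y * (cc - N) / (X - N) else Y }
                else { if (M > X) Y * (M - cc) / (M - X) else Y }
    }
    err <- sum((counts - tri)^2)
    if (err < best_err - 1e-12) { best_err <- err; best <- c(N, M) }
  }
  best[2] - best[1]
}

# A positive interval series with zero mean successive difference
# (first value repeated at the end).
closed_series <- function(n, mean_ms = 200, sd_ms = 10) {
  x <- stats::rnorm(n - 1, mean_ms, sd_ms)
  c(x, x[1])
}
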