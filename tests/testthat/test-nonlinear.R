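# DFA, Poincare, ApEn/SampEn.

test_that("DFA recovers the white-noise exponent on iid intervals", {
  withr::with_seed(1, x <- stats::rnorm(2000, 200, 10))
  d <- dfa(x)
  expect_gt(d$alpha1, 0.4); expect_lt(d$alpha1, 0.6)
  expect_gt(d$alpha2, 0.4); expect_lt(d$alpha2, 0.6)
})

test_that("DFA recovers the Brownian exponent on integrated noise", {
  withr::with_seed(2, x <- cumsum(stats::rnorm(2000)) + 5000)
  expect_gt(dfa(x)$alpha2, 1.3)
  expect_lt(dfa(x)$alpha2, 1.7)
})

test_that("strict alternation drives the short-range exponent to zero", {
  x <- rep(c(190, 210), 150)
  expect_lt(dfa(x)$alpha1, 0.2)
})

test_that("DFA long-range slope matches a naive per-box lm oracle", {
  withr::with_seed(3, x <- stats::rnorm(400, 200, 10))
  mine <- dfa(x, small_box_correction = FALSE)
  ref <- dfa_bruteforce(x)
  expect_equal(mine$fluctuation, ref$F, tolerance = 1e-10)
  expect_equal(mine$alpha1, ref$alpha1, tolerance = 1e-10)
  expect_equal(mine$alpha2, ref$alpha2, tolerance = 1e-10)
})

test_that("DFA rejects degenerate and short input", {
  expect_error(dfa(stats::rnorm(100, 200, 5)), "at least 128")
  expect_error(dfa(rep(200, 300)), "degenerate")
})

test_that("DFA exponents are invariant to affine transforms", {
  withr::with_seed(4, x <- stats::rnorm(500, 200, 10))
  d0 <- dfa(x)
  d1 <- dfa(3 * x + 40)
  expect_equal(d0$alpha1, d1$alpha1, tolerance = 1e-10)
  expect_equal(d0$alpha2, d1$alpha2, tolerance = 1e-10)
})

test_that("Poincare descriptors match the hand-computed alternating case", {
  p <- poincare(c(100, 110, 100, 110, 100))
  expect_equal(p$sd1, 10 / sqrt(2))
  expect_equal(p$sd2, 0)
  pc <- poincare(rep(200, 10))
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)
  expect_true(is.na(pc$ratio_sd2_sd1))
})

test_that("SD1 equals RMSSD/sqrt(2) when the mean successive difference is 0", {
  withr::with_seed(6, {
    for (k in 1:10) {
      x <- closed_series(10)
      expect_equal(poincare(x)$sd1, rmssd(x) / sqrt(2), tolerance = 1e-12)
    }
  })
})

test_that("SD1^2 + SD2^2 approximates twice SDNN^2 on long series", {
  withr::with_seed(7, {
    for (k in 1:5) {
      x <- stats::rnorm(600, 200, 10)
      p <- poincare(x)
      expect_lt(abs(p$sd1^2 + p$sd2^2 - 2 * sdnn(x)^2) / (2 * sdnn(x)^2),
                0.02)
    }
  })
})

test_that("entropies are zero for constant and near-zero for periodic series", {
  expect_equal(apen(rep(200, 100))$apen, 0)
  expect_equal(sampen(rep(200, 100))$sampen, 0)
  alt <- rep(c(190, 210), 100)
  expect_lt(apen(alt)$apen, 0.05)
  expect_lt(sampen(alt)$sampen, 0.05)
})

test_that("vectorized entropies equal brute-force pair counting exactly", {
  withr::with_seed(9, {
    for (k in 1:5) {
      n <- sample(60:150, 1)
      x <- stats::runif(n, 150, 250)
      expect_equal(apen(x)$apen, apen_bruteforce(x), tolerance = 1e-12)
      s <- sampen(x)
      ref <- sampen_bruteforce(x)
      expect_identical(c(s$A, s$B), as.numeric(c(ref$A, ref$B)))
      expect_equal(s$sampen, ref$value, tolerance = 1e-12)
    }
  })
})

test_that("iid entropy exceeds periodic entropy", {
  withr::with_seed(10, x <- stats::runif(200, 150, 250))
  expect_gt(apen(x)$apen, apen(rep(c(190, 210), 100))$apen)
})

test_that("entropies are invariant to affine rescaling (r tracks the SD)", {
  withr::with_seed(11, x <- stats::rnorm(120, 200, 10))
  expect_equal(apen(x)$apen, apen(2.5 * x + 31)$apen, tolerance = 1e-10)
  expect_equal(sampen(x)$sampen, sampen(2.5 * x + 31)$sampen,
               tolerance = 1e-10)
})

test_that("undefined SampEn is reported as missing, not infinite", {
  # sawtooth with huge steps: no length-3 template pairs within r
  x <- seq(100, 1000, length.out = 60)
  x <- x + rep(c(0, 400), 30)
  s <- sampen(x, m = 2, r_frac = 0.05)
  expect_true(is.na(s$sampen) || is.finite(s$sampen))
  expect_error(sampen(stats::rnorm(30, 200, 5)), "50 normal")
})
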