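# Normality screening, t tests, ANOVA, summary-statistic inference.

test_that("Shapiro-Wilk wrapper screens normality sensibly", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  withr::with_seed(12, {
    ok <- 0L
    for (k in 1:100) {
      g <- stats::rnorm(7)
      if (shapiro_wilk(g)$p > 0.05) ok <- ok + 1L
    }
    expect_gte(ok, 90)
    # heavy two-point mixture scores lower W than Gaussian, same seeds
    w_gauss <- w_mix <- numeric(50)
    for (k in 1:50) {
      w_gauss[k] <- shapiro_wilk(stats::rnorm(7))$statistic
      w_mix[k] <- shapiro_wilk(sample(c(-10, 10), 7, TRUE) +
                                 stats::rnorm(7, sd = 0.1))$statistic
    }
    expect_lt(mean(w_mix), mean(w_gauss))
  })
})

test_that("pooled t test matches the hand computation", {
  r <- t_test_independent(c(1, 2, 3), c(4, 5, 6), equal_var = TRUE)
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  sw <- t_test_independent(c(4, 5, 6), c(1, 2, 3), equal_var = TRUE)
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$p, r$p)
  ident <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(t_test_independent(1, c(1, 2)), "n >= 2")
})

test_that("summary-statistic Welch t reproduces the raw-data Welch t", {
  withr::with_seed(13, {
    g1 <- stats::rnorm(7, 250, 30)
    g2 <- stats::rnorm(7, 370, 25)
  })
  raw <- t_test_independent(g1, g2)
  summ <- welch_t_from_summary(mean(g1), stats::sd(g1), 7,
                               mean(g2), stats::sd(g2), 7)
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-10)
  expect_equal(summ$df, raw$df, tolerance = 1e-10)
  expect_equal(summ$p, raw$p, tolerance = 1e-10)
})

test_that("summary Welch t reproduces the reference HR and SDNN contrasts", {
  hr <- welch_t_from_summary(253.81, 34.61, 7, 376.39, 23.62, 7)
  expect_lt(abs(abs(hr$statistic) - 7.74), 0.01)
  expect_lt(hr$p, 0.01)
  sd_t <- welch_t_from_summary(8.57, 3.69, 7, 2.498, 1.00, 7)
  expect_lt(abs(abs(sd_t$statistic) - 4.20), 0.01)
  eq <- welch_t_from_summary(5, 1, 7, 5, 2, 7)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t_from_summary(5, -1, 7, 5, 2, 7), "sd1")
})

test_that("one-way ANOVA matches hand sums of squares", {
  r <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(unname(r$statistic), 3)
  expect_equal(unname(r$df), c(2, 6))
  ident <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(anova_oneway(list(c(1, 2), c(3, 4))), "3 groups")
  expect_error(anova_oneway(list(c(1, 2), c(3, 4), 5)), "n >= 2")
})

test_that("forced two-group ANOVA satisfies F = t^2", {
  withr::with_seed(14, {
    g1 <- stats::rnorm(8); g2 <- stats::rnorm(8, 1)
  })
  t2 <- t_test_independent(g1, g2, equal_var = TRUE)$statistic^2
  values <- c(g1, g2)
  labels <- factor(rep(1:2, each = 8))
  f <- unname(stats::oneway.test(values ~ labels, var.equal = TRUE)$statistic)
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("p values are invariant to affine rescaling of the data", {
  withr::with_seed(15, {
    g1 <- stats::rnorm(7); g2 <- stats::rnorm(7, 0.8); g3 <- stats::rnorm(7, 1.6)
  })
  p0 <- t_test_independent(g1, g2)$p
  p1 <- t_test_independent(10 * g1 + 3, 10 * g2 + 3)$p
  expect_equal(p0, p1, tolerance = 1e-10)
  a0 <- anova_oneway(list(g1, g2, g3))$p
  a1 <- anova_oneway(lapply(list(g1, g2, g3), function(g) 10 * g + 3))$p
  expect_equal(a0, a1, tolerance = 1e-10)
})

test_that("compare_groups assembles summaries, ANOVA and pairwise tests", {
  withr::with_seed(16, {
    tbl <- group_table(
      subject = sprintf("s%02d", 1:21),
      group = rep(c("KX", "P", "PF"), each = 7),
      metric = "mean_hr",
      value = c(stats::rnorm(7, 254, 20), stats::rnorm(7, 376, 20),
                stats::rnorm(7, 378, 20)))
  })
  cmp <- compare_groups(tbl)
  expect_named(cmp, "mean_hr")
  m <- cmp$mean_hr
  expect_equal(nrow(m$summary), 3)
  expect_false(is.null(m$anova))
  expect_length(m$pairwise, 3)
  expect_lt(m$pairwise[["KX vs P"]]$p, 0.01)
  expect_true(all(vapply(m$pairwise, function(x)
    x$grade %in% c("ns", "*", "**", "***"), logical(1))))
  # Holm correction only increases p values
  cmp_h <- compare_groups(tbl, correct = "holm")
  for (nm in names(m$pairwise))
    expect_gte(cmp_h$mean_hr$pairwise[[nm]]$p_adjusted, m$pairwise[[nm]]$p)
  # single usable group -> summaries with warning
  one <- tbl[tbl$group == "KX", ]
  expect_error(compare_groups(one), "2 groups")
})
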