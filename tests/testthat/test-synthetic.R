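# IPFM RR generator and ECG synthesis.

test_that("unmodulated IPFM emits a metronomic beat train", {
  rr <- generate_rr_series(modulation_spec(200, total_sd = 0), 60)
  expect_true(all(rr$intervals == 200))
  expect_equal(length(rr$intervals), 299)  # beats at 0.2, 0.4, ..., 60 s
})

test_that("generator rejects invalid requests", {
  expect_error(modulation_spec(-5), "mean_rr")
  expect_error(modulation_spec(200, frac_hf = 0.7, frac_lf = 0.5), "sum")
  expect_error(generate_rr_series(modulation_spec(200), 10), "duration")
  # variability so large the rate would cross zero
  expect_error(
    generate_rr_series(modulation_spec(200, frac_lf = 1, total_sd = 190),
                       60, seed = 1),
    "zero")
})

test_that("identical (spec, duration, seed) triples are bit-identical", {
  spec <- group_preset("P")$modulation
  a <- generate_rr_series(spec, 60, seed = 42)
  b <- generate_rr_series(spec, 60, seed = 42)
  expect_identical(a, b)
  c <- generate_rr_series(spec, 60, seed = 43)
  expect_false(identical(a$intervals, c$intervals))
})

test_that("beat count is conserved for fractal-only specs", {
  for (seed in 1:5) {
    spec <- modulation_spec(180, total_sd = 6, beta = 1)
    rr <- generate_rr_series(spec, 120, seed = seed)
    n <- length(rr$intervals) + 1
    expect_lt(abs(n - 120000 / 180), 2 + 3 * 6 / 180 * sqrt(n))
  }
})

test_that("KX preset mean HR matches its calibration level within 2%", {
  rr <- generate_rr_series(group_preset("KX")$modulation, 300, seed = 11)
  expect_lt(abs(mean_hr(rr) - 253.81) / 253.81, 0.02)
  expect_lt(abs(sdnn(rr) - 8.57) / 8.57, 0.15)
})

test_that("an HF-dominated spec concentrates resampled power in HF", {
  spec <- modulation_spec(150, frac_hf = 0.9, total_sd = 5)
  rr <- generate_rr_series(spec, 300, seed = 3)
  bands <- frequency_domain_metrics(rr)$bands
  expect_gte(bands$hf_rel, 80)
})

test_that("single-band specs put the dominant band where requested", {
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    for (band in c("vlf", "lf", "hf")) {
      args <- list(mean_rr = 150, total_sd = 5)
      args[[paste0("frac_", band)]] <- 0.9
      rr <- generate_rr_series(do.call(modulation_spec, args), 120, seed = seed)
      u <- berger_resample(rr)
      bp <- band_powers(welch_psd(u, window = 30))
      rel <- c(vlf = bp$vlf_rel, lf = bp$lf_rel, hf = bp$hf_rel)
      total <- total + 1L
      if (names(which.max(rel)) == band) hits <- hits + 1L
    }
  }
  expect_equal(hits, total)
})

test_that("group presets encode the anesthesia-group levels and ordering", {
  expect_equal(group_preset("KX")$modulation$mean_rr, 60000 / 253.81)
  expect_equal(group_preset("PF")$modulation$mean_rr, 60000 / 377.99,
               tolerance = 1e-12)
  expect_lt(abs(group_preset("KX")$modulation$mean_rr - 236.4), 0.1)
  sds <- sapply(c("KX", "P", "PF"),
                function(g) group_preset(g)$modulation$total_sd)
  expect_true(all(diff(sds) < 0))  # KX > P > PF
  expect_error(group_preset("xx"), "KX, P, PF")
})

test_that("ECG synthesis places one complex per beat with R at the beat time", {
  rr <- generate_rr_series(modulation_spec(200, total_sd = 0), 60)
  tmpl <- ecg_template(noise_sd = 0, baseline_wander_amp = 0)
  out <- generate_ecg(rr, fs = 4000, template = tmpl)
  expect_equal(length(out$truth_times), 300)
  x <- out$ecg$samples
  fs <- out$ecg$fs
  for (b in out$truth_times[c(1, 150, 300)]) {
    win <- round((b + c(-0.05, 0.05)) * fs) + 1L
    win[1] <- max(1L, win[1]); win[2] <- min(length(x), win[2])
    i_max <- which.max(x[win[1]:win[2]]) + win[1] - 1L
    expect_lt(abs((i_max - 1) / fs - b), 1.5 / fs + 1e-12)
  }
})

test_that("zero-amplitude template yields noise-only trace", {
  rr <- generate_rr_series(modulation_spec(200, total_sd = 0), 30)
  waves <- data.frame(wave = c("P", "Q", "R", "S", "T"), amp = 0,
                      offset = c(-25, -6, 0, 6, 25), width = c(5, 2, 2.5, 2, 8))
  tmpl <- ecg_template(waves, baseline_wander_amp = 0, noise_sd = 0.01)
  out <- generate_ecg(rr, fs = 1000, template = tmpl, seed = 1)
  expect_lt(max(abs(out$ecg$samples)), 0.1)
})

test_that("template footprint wider than the beat spacing is rejected", {
  rr <- generate_rr_series(modulation_spec(40, total_sd = 0), 30)
  expect_error(generate_ecg(rr, fs = 1000), "footprint")
})

test_that("template invariants are enforced", {
  waves <- data.frame(wave = c("R", "T"), amp = c(0.1, 0.5),
                      offset = c(0, 25), width = c(2.5, 8))
  expect_error(ecg_template(waves), "R wave")
  waves2 <- data.frame(wave = "R", amp = 1, offset = 0, width = -1)
  expect_error(ecg_template(waves2), "width")
})
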