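# Pan-Tompkins detection, tachogram construction, ectopy flagging,
# Berger resampling.

clean_ecg <- function(hr, duration = 60, total_sd = 5, seed = 1) {
  spec <- modulation_spec(60000 / hr, frac_vlf = 0.3, frac_lf = 0.2,
                          frac_hf = 0.2, total_sd = total_sd)
  rr <- generate_rr_series(spec, duration, seed = seed)
  generate_ecg(rr, fs = 4000,
               template = ecg_template(noise_sd = 0, baseline_wander_amp = 0),
               seed = seed)
}

test_that("clean 300 bpm ECG is recovered beat for beat", {
  out <- clean_ecg(300, seed = 2)
  det <- pan_tompkins_detect(out$ecg)
  expect_lte(abs(length(det$times) - length(out$truth_times)), 1)
  m <- match_peaks(det$times, out$truth_times)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1)
  expect_lt(m$max_err, 0.0025)
})

test_that("noisy default-template ECG is recovered at >= 99.5%", {
  rr <- generate_rr_series(group_preset("KX")$modulation, 60, seed = 5)
  out <- generate_ecg(rr, fs = 4000, template = ecg_template(), seed = 5)
  det <- pan_tompkins_detect(out$ecg)
  m <- match_peaks(det$times, out$truth_times)
  expect_gte(m$sensitivity, 0.995)
  expect_gte(m$ppv, 0.995)
})

test_that("a flat trace yields zero peaks with a warning", {
  flat <- ecg_record(rep(0.3, 10000), fs = 1000)
  expect_warning(det <- pan_tompkins_detect(flat), "constant")
  expect_length(det$times, 0)
})

test_that("sign-inverted lead gives the same beats in polarity-agnostic mode", {
  out <- clean_ecg(300, seed = 7)
  inv <- ecg_record(-out$ecg$samples, out$ecg$fs)
  det <- pan_tompkins_detect(inv, detector_params(polarity = "absolute"))
  m <- match_peaks(det$times, out$truth_times)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1)
})

test_that("detected tachogram reproduces the generator intervals", {
  out <- clean_ecg(330, seed = 9)
  rr <- rr_from_peaks(pan_tompkins_detect(out$ecg))
  truth_rr <- diff(out$truth_times) * 1000
  expect_equal(length(rr$intervals), length(truth_rr))
  expect_lt(max(abs(rr$intervals - truth_rr)), 2.5)
})

test_that("rr_from_peaks converts times to ms intervals", {
  rr <- rr_from_peaks(r_peaks(c(0, 0.2, 0.4, 0.6)))
  expect_equal(rr$intervals, c(200, 200, 200))
  rr2 <- rr_from_peaks(r_peaks(c(0, 0.2, 0.5)))
  expect_equal(rr2$intervals, c(200, 300))
  expect_error(rr_from_peaks(r_peaks(c(0, 0.2))), "3 peaks")
  expect_error(r_peaks(c(0.2, 0.1)), "increasing")
})

test_that("nn_filter flags exactly the inserted ectopic-like interval", {
  x <- rep(200, 50)
  rr <- rr_series(x)
  expect_true(all(nn_filter(rr, 0.2)$normal))
  x[25] <- 400
  flagged <- nn_filter(rr_series(x), 0.2)
  expect_equal(which(!flagged$normal), 25L)
  expect_error(nn_filter(rr, 1.5), "between 0 and 1")
})

test_that("Berger resampling of a constant tachogram is exact", {
  rr <- rr_series(rep(150, 400))
  u <- berger_resample(rr, fs_out = 10)
  expect_equal(u$fs_out, 10)
  expect_true(all(abs(u$values - 150) < 1e-9))
  expect_error(berger_resample(rr_series(c(150, 150))), "3 normal")
})

test_that("Berger output crosses a step monotonically between the levels", {
  rr <- rr_series(c(rep(150, 400), rep(200, 300)))
  u <- berger_resample(rr, fs_out = 10)
  expect_true(all(diff(u$values) > -1e-9))
  expect_equal(u$values[5], 150)
  expect_equal(u$values[length(u$values) - 5], 200)
})

test_that("Berger resampling is invariant to a global time shift", {
  set.seed(31)
  ints <- stats::rnorm(300, 180, 8)
  rr1 <- rr_series(ints)
  rr2 <- rr_series(ints, beat_times = cumsum(ints) / 1000 + 17.37)
  expect_equal(berger_resample(rr1)$values, berger_resample(rr2)$values)
})

test_that("resampled mean matches the NN mean within 1% for all presets", {
  for (g in c("KX", "P", "PF")) {
    rr <- generate_rr_series(group_preset(g)$modulation, 120, seed = 4)
    u <- berger_resample(rr)
    expect_lt(abs(mean(u$values) - mean(rr$intervals)) / mean(rr$intervals),
              0.01)
  }
})
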