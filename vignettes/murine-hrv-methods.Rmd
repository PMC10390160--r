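---
title: "Methods: murine heart rate variability analysis in mousehrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: murine heart rate variability analysis in mousehrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousehrv)
```

## Scope and model of the data

`mousehrv` analyzes short (4–5 minute) single-lead ECG recordings from
anesthetized mice, or the RR-interval tachograms derived from them, and
produces the standard heart rate variability (HRV) battery: time-domain
indices (SDNN, RMSSD, TINN, mean HR), spectral band powers over the
murine bands, detrended fluctuation analysis (DFA), Poincaré plot
descriptors, and approximate/sample entropy, plus the group-comparison
statistics used in small-animal anesthesia studies (Shapiro–Wilk
screening, Welch/pooled t tests, one-way ANOVA, and inference directly
from published mean ± SD summaries).

Murine physiology drives several constants that differ from the human
defaults and are therefore explicit, configurable parameters:

* **Spectral bands**: VLF 0–0.15 Hz, LF 0.15–1.5 Hz, HF 1.5–5 Hz.
  Murine respiratory and baroreflex rhythms sit an order of magnitude
  above the human ones, so the human 0.04/0.15/0.4 Hz edges are
  meaningless here.
* **Resampling rate**: tachograms are converted to a uniform 10 Hz
  interval signal, giving a 5 Hz Nyquist limit that just covers the HF
  band.
* **Detector timing**: murine QRS complexes are ~10 ms wide; the
  Pan-Tompkins constants are rescaled accordingly (band-pass 10–100 Hz,
  15 ms integration window, 50 ms refractory period, searchback factor
  1.66). All are fields of `detector_params()`.
* **TINN bin width**: 1 ms (the human-standard 1/128 s ≈ 7.8 ms bin is
  wider than a typical murine NN histogram).

## Pipeline

`run_subject()` executes: Pan-Tompkins detection (for ECG input) →
tachogram construction → optional ectopy screening → the four metric
families. Every stage failure is captured per family, so a report is
always produced with explicit missing markers — a 40-beat file still
yields time-domain numbers while DFA and entropy are marked "too
short" with their reasons.

### R-peak detection

The detector follows the classic stage sequence — band-pass, five-point
derivative, squaring, moving-window integration, dual adaptive
thresholds with running signal/noise peak estimates
(new = ⅛·peak + ⅞·old), refractory blanking, and half-threshold
searchback when the gap since the last beat exceeds 1.66 times the
running RR average. Two numerical choices matter for RR precision,
which feeds every downstream metric:

* the band-pass is applied forward–backward (zero phase) and the
  derivative/integration kernels are centered, so the integrated-signal
  fiducial carries no group delay;
* each fiducial is then refined to the local extremum of the *raw*
  trace within ± one integration window, with a polarity mode
  (`auto`/`positive`/`absolute`) so inverted leads are handled.

On noise-free synthetic ECG between 250 and 380 bpm the detector
recovers every beat with timing error well below 2.5 ms (the test suite
and `scripts/acceptance.R` recompute this over 50 records).

### Berger resampling

Spectral analysis needs a uniformly sampled signal. For each 10 Hz
output sample, a window of width 2/fs spanning the sample counts the
fractional number of beat intervals it overlaps; the local rate is
fs/2 × count and the stored value is the equivalent interval in ms.
The output grid is anchored to the beat train, making the values
invariant to a global time shift, and edge samples whose window would
leave the record are dropped rather than padded — no fabricated data at
the boundaries. Intervals flagged non-normal are merged with their
successor inside the counting window. Interval (ms) rather than rate
(bpm) output keeps spectral powers in the conventional ms² units.

### Spectral estimation

The estimator is Welch averaging of Hann-tapered, 50%-overlapped 60 s
segments with per-segment mean and linear-trend removal. The averaged
density is given a variance-preserving normalization: it is rescaled so
that its integral equals the mean variance of the detrended
(untapered) segments. Without this step the taper's center-weighting
makes the integral match the signal variance only in expectation, with
a few percent of realization-to-realization scatter; with it, Parseval
holds for every input (the sinusoid benchmark integrates to
amplitude²/2 within 0.2%). Band integration is trapezoidal with each
spectral sub-interval assigned to the band containing its midpoint, the
0 Hz bin excluded; total power is defined as VLF+LF+HF so the three
relative powers sum to 100% by construction.

Per-segment *linear* detrending is deliberate: smoothness-prior or
higher-order detrending schemes found in interactive HRV tools are not
reproduced, because they add a tuning parameter with no agreed value.
Consequently VLF power below 1/60 Hz is partly removed with the trend;
with 4-minute recordings nothing below that frequency is resolvable
anyway.

### Detrended fluctuation analysis

The NN series is integrated about its mean; for each box size n in
4…64 the profile is split into floor(N/n) non-overlapping boxes from
the start (tail discarded), a least-squares line is removed per box,
and F(n) is the RMS of the residuals over the covered length. α1 and
α2 are the log–log slopes over the inclusive integer ranges 4–11 and
12–64 — the inclusive reading matches the convention of starting the
short-range fit at 4 beats; the strict-exclusive reading is available
via `inclusive = FALSE`.

Linear-detrend DFA is biased at small boxes: for an uncorrelated
series E[F²(n)] = σ²(n²−4)/(15n), not ∝ n, which inflates the
short-range slope from 0.5 to ≈ 0.62. By default `dfa()` divides F(n)
by √(1−4/n²), the exact finite-box factor for uncorrelated input. The
correction restores α = 0.5 scaling for white noise at every box size,
changes the 12–64 beat slope by less than 0.01 (Brownian input still
fits α2 ≈ 1.5), and can be disabled with
`small_box_correction = FALSE`, which reproduces the plain textbook
estimator exactly (the tests verify this against an independent
per-box `lm()` oracle).

### Poincaré and entropy

SD1/SD2 are the standard deviations of (x−y)/√2 and (x+y)/√2 over the
successive-interval pairs, with the pair count as denominator. This
makes the identity SD1 = RMSSD/√2 *exact* whenever the mean successive
difference is zero, and SD1² + SD2² ≈ 2·SDNN² to within end effects —
both are enforced in the tests. When SD1 = 0 the SD2/SD1 ratio is
reported as missing, not as infinity.

ApEn includes self-matches (Φ^m − Φ^{m+1} over all templates); SampEn
excludes them and counts ordered pairs over a common template set of
the first N−m positions — the defining difference between the two
statistics. Distance is Chebyshev; the tolerance r defaults to 20% of
the series SD (r is recomputed per series, which makes both entropies
exactly invariant under affine rescaling), and m defaults to 2. Both
implementations are verified to machine precision against brute-force
O(N²) pair counting. An undefined SampEn (no length-(m+1) matches) is
reported as a missing value with the pair counts attached, keeping
group tables numeric with explicit missingness.

### Analysis domain

One published description of this workflow can be read as computing
*all* metrics on the 10 Hz interpolated signal. The conventional
practice — and the default here (`analysis_domain = "beats"`) — is to
compute time-domain and nonlinear metrics on the beat-domain NN list
and only the spectrum on the interpolated signal;
`analysis_domain = "interpolated"` gives the literal reading.

## The synthetic generator

Because no public murine recordings accompany this workflow, the
package ships a first-class generator so every stage is testable.

Beat trains come from integral pulse frequency modulation (IPFM): a
modulating signal m(t) — a 0.15 Hz-low-passed Gaussian drift (VLF),
sinusoidal carriers at 0.4 and 2.5 Hz (the murine LF and HF band
midpoints; the bands' carrier frequencies are otherwise unspecified,
so midpoints are the neutral choice), and FFT-shaped 1/f^β Gaussian
noise — is folded into the rate 1/(mean_rr·(1+m(t))) and integrated; a
beat fires at each integer crossing. IPFM guarantees positive
intervals and produces beat-train spectra that mirror the modulation,
which is why it is the standard generator for validating HRV software.
Component amplitudes are set from the requested band fractions and
rescaled once against a pilot run so the realized RR standard
deviation matches the target; exact fraction matching is not promised
(the Berger window attenuates power near the 2.5 Hz carrier), only
dominant-band placement, which the tests check across seeds.

ECG synthesis places Gaussian P-QRS-T bumps (QRS ≈ 10 ms wide,
R-amplitude dominant) at each beat time and adds slow sinusoidal
baseline wander and white noise; ground-truth R times are returned for
detector validation.

The three presets are calibrated to the reference group levels of a
ketamine+xylazine vs pentobarbital vs pentobarbital+fentanyl
comparison: mean RR = 60000/253.81, 60000/376.39 and 60000/377.99 ms
and SDNN targets 8.57, 4.58 and 2.498 ms respectively. The band
mixtures are statistical mimics chosen once: KX is HF-dominated
(fractions 0.20/0.15/0.50 VLF/LF/HF), which produces the high
RMSSD/SD1 and low SD2/SD1 seen under ketamine+xylazine, while P
(0.45/0.25/0.10) and PF (0.40/0.30/0.10) are drift-dominated. What the
presets do **not** emulate: pharmacokinetics, respiration as a
co-signal, ectopy, electrode artifacts, or non-stationarity within a
recording. Passing the study-level ordering tests therefore shows that
the *pipeline* orders the groups correctly given their statistical
structure — not that real recordings would be classified correctly.

## Statistics

Pairwise tests default to Welch (the reference group SDs differ up to
four-fold, so pooling is not defensible as a default); pooled t is a
flag. `welch_t_from_summary()` reproduces `t_test_independent()` on
raw data to 10 decimal places and lets printed mean ± SD ± n tables be
audited directly — on the reference heart-rate summaries it gives
|t| = 7.74 (KX vs P) and 5.96 (KX vs PF), both p < 0.01. No
multiple-comparison correction is applied by default, matching common
reporting practice in this literature; Holm correction is available
behind a flag. Reports print exact p values plus the graded
*/**/*** marks at 0.05/0.01/0.001.

## Problem sizes and determinism

The test suite and acceptance script use 60–300 s synthetic records,
50-seed detector sweeps, N = 2000 DFA calibrations (20 seeds), N ≤ 300
brute-force entropy cross-checks (50 series), and one full 3 × 7 study
of 5-minute records — sizes chosen to estimate each quantity stably
while keeping a full run in minutes on a laptop. All randomness flows
through explicit integer seeds (`withr::with_seed`), and identical
(spec, duration, seed) triples are bit-identical, as are repeated
reports from the same input and configuration.

## Known limitations

* The ectopy screen (running-median rule, 20% deviation limit) is a
  generic stand-in: no artifact-rejection criterion is standardized
  for anesthetized mice, and it defaults to off.
* TINN's exhaustive baseline search is exact but O(bins³); at the 1 ms
  default with murine spreads this is instantaneous, but very wide
  histograms at fine bins would be slow.
* Welch resolution (1/60 Hz) cannot separate structure inside the VLF
  band of a 4-minute recording; VLF power is reported as a single
  integral.
* SampEn on short, low-variability series can be undefined (A = 0);
  it is reported as missing, and group comparisons simply drop the
  missing subject for that metric.

```{r example, eval = FALSE}
# A complete synthetic subject, end to end
rr <- generate_rr_series(group_preset("KX")$modulation, 300, seed = 11)
report <- run_subject(rr, subject = "kx11")
print(report)

# A full 3 x 7 study with the statistical layer
st <- simulate_study(n_per_group = 7, duration = 300, seed = 7)
study <- run_study(st$subjects, st$manifest)
print(study$comparison)
```
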