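# End-to-end orchestration: configuration, per-subject reports, and
# study-level comparison.

#' Pipeline configuration
#'
#' Bundles and validates every tunable of the pipeline. Defaults follow
#' murine conventions throughout: 10 Hz resampling, murine spectral band
#' edges, DFA fit ranges 4-11 / 12-64 beats, entropy m = 2 with r = 20%
#' of the series SD, 1 ms TINN bins. `analysis_domain` selects whether
#' time-domain and nonlinear metrics are computed on the beat-domain NN
#' list (`"beats"`, conventional default) or on the 10 Hz interpolated
#' signal (`"interpolated"`, the literal single-time-series reading).
#'
#' @param detector A [detector_params()].
#' @param fs_out Uniform resampling rate in Hz.
#' @param band_edges `c(vlf_hi, lf_hi, hf_hi)` in Hz.
#' @param dfa_range1,dfa_range2 DFA fit ranges in beats.
#' @param entropy_m,entropy_r_frac Entropy parameters.
#' @param tinn_bin TINN histogram bin width in ms.
#' @param welch_window,welch_overlap Welch segmentation.
#' @param nn_filter_on,nn_deviation_limit Ectopy screening (off by
#'   default; synthetic data contain no ectopy).
#' @param analysis_domain `"beats"` or `"interpolated"`.
#' @param seed Integer seed recorded in reports.
#' @return A validated list of class `pipeline_config`.
#' @export
hrv_config <- function(detector = detector_params(), fs_out = 10,
                       band_edges = c(0.15, 1.5, 5),
                       dfa_range1 = c(4, 11), dfa_range2 = c(12, 64),
                       entropy_m = 2, entropy_r_frac = 0.2, tinn_bin = 1,
                       welch_window = 60, welch_overlap = 0.5,
                       nn_filter_on = FALSE, nn_deviation_limit = 0.2,
                       analysis_domain = c("beats", "interpolated"),
                       seed = NULL) {
  check_number(fs_out, "fs_out", lower = 1e-9)
  if (length(band_edges) != 3 || any(diff(band_edges) <= 0))
    stopf("`band_edges` must be three increasing frequencies")
  if (band_edges[3] > fs_out / 2 + 1e-9)
    stopf("highest band edge must not exceed fs_out/2")
  check_number(entropy_m, "entropy_m", lower = 1)
  check_number(entropy_r_frac, "entropy_r_frac", lower = 1e-6, upper = 1)
  check_number(tinn_bin, "tinn_bin", lower = 1e-9)
  check_number(welch_window, "welch_window", lower = 1)
  structure(list(detector = detector, fs_out = fs_out,
                 band_edges = band_edges,
                 dfa_range1 = dfa_range1, dfa_range2 = dfa_range2,
                 entropy_m = entropy_m, entropy_r_frac = entropy_r_frac,
                 tinn_bin = tinn_bin, welch_window = welch_window,
                 welch_overlap = welch_overlap,
                 nn_filter_on = nn_filter_on,
                 nn_deviation_limit = nn_deviation_limit,
                 analysis_domain = match.arg(analysis_domain),
                 seed = seed),
            class = "pipeline_config")
}

# evaluate a metric family, capturing the failure reason instead of
# aborting the report
try_metric <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr),
           error = function(e) list(ok = FALSE, value = NULL,
                                    reason = conditionMessage(e)))
}

#' Analyze one subject end to end
#'
#' Accepts a raw ECG (record or CSV path) or an RR series (object or
#' plain-text path). ECG input is run through Pan-Tompkins detection and
#' tachogram construction; then, per `config`: optional ectopy
#' screening, time-domain, Berger + Welch frequency-domain, DFA,
#' Poincare and entropy metrics. Any stage failure is captured in the
#' report as an explicit missing marker with its reason; the report is
#' always produced.
#'
#' @param input An [ecg_record()], [rr_series()], or path to an ECG CSV
#'   / RR text file (files ending in `.rr` or `.txt` are read as RR).
#' @param config A [hrv_config()].
#' @param subject Subject identifier stored in the report.
#' @return A list of class `hrv_report`.
#' @export
run_subject <- function(input, config = hrv_config(), subject = "subject") {
  if (is.character(input)) {
    if (!file.exists(input)) stopf("input file not found: %s", input)
    input <- if (grepl("\\.(rr|txt)$", input)) read_rr(input)
             else read_ecg_csv(input)
  }
  meta <- list(subject = subject, fs = NA_real_, duration = NA_real_,
               n_detected = NA_integer_, n_flagged = 0L,
               version = as.character(utils::packageVersion("mousehrv")),
               seed = config$seed)

  if (inherits(input, "ecg_record")) {
    meta$fs <- input$fs
    meta$duration <- length(input$samples) / input$fs
    peaks <- pan_tompkins_detect(input, config$detector)
    rr <- rr_from_peaks(peaks)
    meta$n_detected <- length(peaks$times)
  } else if (inherits(input, "rr_series")) {
    rr <- input
    meta$duration <- sum(rr$intervals) / 1000
  } else stopf("`input` must be an ECG record, an RR series, or a file path")

  if (config$nn_filter_on) {
    rr <- nn_filter(rr, config$nn_deviation_limit)
    meta$n_flagged <- sum(!rr$normal)
  }

  freq <- try_metric({
    u <- berger_resample(rr, fs_out = config$fs_out)
    sp <- welch_psd(u, window = config$welch_window,
                    overlap = config$welch_overlap)
    band_powers(sp, edges = config$band_edges)
  })

  # beat-domain NN list, or the interpolated signal under the literal
  # single-time-series reading
  nn_input <- if (config$analysis_domain == "interpolated" && freq$ok)
    berger_resample(rr, fs_out = config$fs_out)$values else rr

  structure(list(
    subject = subject, meta = meta, n_beats = length(rr$intervals),
    time_domain = try_metric(time_domain_metrics(nn_input,
                                                 bin_width = config$tinn_bin)),
    frequency = freq,
    dfa = try_metric(dfa(nn_input, config$dfa_range1, config$dfa_range2)),
    poincare = try_metric(poincare(nn_input)),
    entropy = try_metric({
      a <- apen(nn_input, config$entropy_m, config$entropy_r_frac)
      s <- sampen(nn_input, config$entropy_m, config$entropy_r_frac)
      list(apen = a, sampen = s)
    })),
    class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat(sprintf("HRV report for %s (%d beats)\n", x$subject, x$n_beats))
  show <- function(name, fam) {
    if (fam$ok) print(fam$value)
    else cat(sprintf("%s: missing (%s)\n", name, fam$reason))
  }
  show("time domain", x$time_domain)
  if (x$frequency$ok) print(x$frequency$value)
  else cat(sprintf("frequency domain: missing (%s)\n", x$frequency$reason))
  show("DFA", x$dfa)
  show("Poincare", x$poincare)
  if (x$entropy$ok) { print(x$entropy$value$apen); print(x$entropy$value$sampen) }
  else cat(sprintf("entropy: missing (%s)\n", x$entropy$reason))
  invisible(x)
}

#' Flatten an HRV report to a named numeric vector
#'
#' One value per scalar metric; metrics whose stage failed are `NA`.
#'
#' @param report An `hrv_report`.
#' @return Named numeric vector.
#' @export
report_metrics <- function(report) {
  g <- function(fam, f) if (fam$ok) f(fam$value) else NA_real_
  c(mean_hr = g(report$time_domain, function(v) v$mean_hr),
    mean_nn = g(report$time_domain, function(v) v$mean_nn),
    sdnn = g(report$time_domain, function(v) v$sdnn),
    rmssd = g(report$time_domain, function(v) v$rmssd),
    tinn = g(report$time_domain, function(v) v$tinn),
    vlf_rel = g(report$frequency, function(v) v$vlf_rel),
    lf_rel = g(report$frequency, function(v) v$lf_rel),
    hf_rel = g(report$frequency, function(v) v$hf_rel),
    lf_hf = g(report$frequency, function(v) v$lf_hf),
    total_power = g(report$frequency, function(v) v$total_power),
    dfa_alpha1 = g(report$dfa, function(v) v$alpha1),
    dfa_alpha2 = g(report$dfa, function(v) v$alpha2),
    sd1 = g(report$poincare, function(v) v$sd1),
    sd2 = g(report$poincare, function(v) v$sd2),
    sd2_sd1 = g(report$poincare, function(v) v$ratio_sd2_sd1),
    apen = g(report$entropy, function(v) v$apen$apen),
    sampen = g(report$entropy, function(v) v$sampen$sampen))
}

#' Serialize an HRV report to JSON
#'
#' @param report An `hrv_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(subject = report$subject, meta = report$meta,
                  n_beats = report$n_beats,
                  metrics = as.list(report_metrics(report)),
                  missing = Filter(Negate(is.null), list(
                    time_domain = if (!report$time_domain$ok) report$time_domain$reason,
                    frequency = if (!report$frequency$ok) report$frequency$reason,
                    dfa = if (!report$dfa$ok) report$dfa$reason,
                    poincare = if (!report$poincare$ok) report$poincare$reason,
                    entropy = if (!report$entropy$ok) report$entropy$reason)))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Run a multi-subject study
#'
#' Analyzes every subject in the manifest, assembles the tidy
#' subjects-by-metrics [group_table()], runs [compare_groups()], and
#' summarizes each metric as mean +/- SD per group.
#'
#' @param subjects Named list of inputs accepted by [run_subject()]
#'   (RR series, ECG records, or file paths).
#' @param manifest Data frame with columns `subject` (matching the names
#'   of `subjects`) and `group`; >= 2 groups with >= 2 subjects each.
#' @param config A [hrv_config()].
#' @return A list of class `hrv_study`: `reports`, `table`
#'   (a [group_table()]), `comparison`, `failed` (character).
#' @export
run_study <- function(subjects, manifest, config = hrv_config()) {
  if (!all(c("subject", "group") %in% names(manifest)))
    stopf("`manifest` needs columns subject and group")
  if (length(unique(manifest$group)) < 2)
    stopf("need at least 2 groups")

  reports <- list()
  failed <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject[i]
    rep_i <- tryCatch(run_subject(subjects[[id]], config, subject = id),
                      error = function(e) e)
    if (inherits(rep_i, "error")) {
      warnf("subject %s failed: %s", id, conditionMessage(rep_i))
      failed <- c(failed, id)
    } else reports[[id]] <- rep_i
  }
  ok <- manifest[manifest$subject %in% names(reports), ]
  sizes <- table(ok$group)
  if (length(sizes) < 2 || any(sizes < 2))
    stopf("after failures, fewer than 2 groups with >= 2 subjects remain")

  rows <- do.call(rbind, lapply(names(reports), function(id) {
    m <- report_metrics(reports[[id]])
    data.frame(subject = id,
               group = ok$group[match(id, ok$subject)],
               metric = names(m), value = unname(m))
  }))
  tbl <- group_table(rows$subject, rows$group, rows$metric, rows$value)
  structure(list(reports = reports, table = tbl,
                 comparison = compare_groups(tbl),
                 failed = failed),
            class = "hrv_study")
}

#' @export
print.hrv_study <- function(x, ...) {
  cat(sprintf("HRV study: %d subjects, %d groups%s\n",
              length(x$reports), length(unique(x$table$group)),
              if (length(x$failed)) sprintf(" (%d failed)", length(x$failed))
              else ""))
  print(x$comparison)
  invisible(x)
}

#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Unknown keys are an error; values are validated
#' by [hrv_config()].
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_hrv_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stopf("malformed config line: '%s'", lines[bad][1])
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  args <- list()
  numkeys <- c("fs_out", "entropy_m", "entropy_r_frac", "tinn_bin",
               "welch_window", "welch_overlap", "nn_deviation_limit", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% numkeys) args[[k]] <- as.numeric(vals[i])
    else if (k == "analysis_domain") args[[k]] <- vals[i]
    else if (k == "nn_filter_on") args[[k]] <- as.logical(vals[i])
    else if (k %in% c("band_edges", "dfa_range1", "dfa_range2"))
      args[[k]] <- as.numeric(strsplit(vals[i], ",")[[1]])
    else stopf("unknown config key '%s'", k)
  }
  do.call(hrv_config, args)
}

#' Print the default configuration as flat key-value text
#'
#' @param config A `pipeline_config` (default: the package defaults).
#' @return Character vector of `key = value` lines, invisibly; also
#'   printed.
#' @export
show_hrv_config <- function(config = hrv_config()) {
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = ",")
  lines <- c(
    sprintf("fs_out = %s", fmt(config$fs_out)),
    sprintf("band_edges = %s", fmt(config$band_edges)),
    sprintf("dfa_range1 = %s", fmt(config$dfa_range1)),
    sprintf("dfa_range2 = %s", fmt(config$dfa_range2)),
    sprintf("entropy_m = %s", fmt(config$entropy_m)),
    sprintf("entropy_r_frac = %s", fmt(config$entropy_r_frac)),
    sprintf("tinn_bin = %s", fmt(config$tinn_bin)),
    sprintf("welch_window = %s", fmt(config$welch_window)),
    sprintf("welch_overlap = %s", fmt(config$welch_overlap)),
    sprintf("nn_filter_on = %s", config$nn_filter_on),
    sprintf("nn_deviation_limit = %s", fmt(config$nn_deviation_limit)),
    sprintf("analysis_domain = %s", config$analysis_domain))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
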