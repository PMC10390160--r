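# Plain-text readers and writers for the pipeline's file formats:
# ECG as two-column CSV (time_s, mv) with a key-value comment header,
# RR series as one ms value per line, peak annotations as one time in
# seconds per line, group tables as tidy CSV.

#' Write an ECG record to CSV
#'
#' Two numeric columns `time_s, mv`, preceded by `# key: value` header
#' lines carrying the sampling rate and any extra metadata.
#'
#' @param ecg An [ecg_record()].
#' @param path Output file path.
#' @param meta Named character/numeric vector of extra header fields
#'   (e.g. seed, preset).
#' @export
write_ecg_csv <- function(ecg, path, meta = NULL) {
  if (!inherits(ecg, "ecg_record")) stopf("`ecg` must be an ecg_record")
  hdr <- c(sprintf("# fs_hz: %.10g", ecg$fs),
           sprintf("# start_time_s: %.10g", ecg$start_time))
  if (!is.null(meta))
    hdr <- c(hdr, sprintf("# %s: %s", names(meta), as.character(meta)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_s,mv"), con)
  tvec <- ecg$start_time + (seq_along(ecg$samples) - 1) / ecg$fs
  utils::write.table(data.frame(time_s = tvec, mv = ecg$samples), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Accepts files written by [write_ecg_csv()] or any two-column numeric
#' text; the sampling rate is taken from the `# fs_hz:` header unless
#' overridden by `fs`.
#'
#' @param path Input file path.
#' @param fs Optional sampling-rate override in Hz.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(fs)) {
    m <- grep("^# fs_hz:", hdr, value = TRUE)
    if (length(m) == 1) fs <- as.numeric(sub("^# fs_hz:", "", m))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!is.numeric(df[[1]])) df <- utils::read.csv(path, comment.char = "#",
                                                  header = FALSE)
  if (is.null(fs)) {
    dt <- stats::median(diff(df[[1]]))
    if (!is.finite(dt) || dt <= 0) stopf("cannot infer sampling rate; pass `fs`")
    fs <- 1 / dt
  }
  ecg_record(df[[2]], fs = fs, start_time = df[[1]][1])
}

#' Write an RR series as plain text, one ms value per line
#' @param rr An [rr_series()].
#' @param path Output file path.
#' @export
write_rr <- function(rr, path) {
  if (!inherits(rr, "rr_series")) stopf("`rr` must be an rr_series")
  writeLines(format(rr$intervals, digits = 15, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read an RR series from plain text (one ms value per line)
#' @param path Input file path.
#' @return An [rr_series()] (beat times rebuilt by cumulative sum).
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- as.numeric(readLines(path))
  x <- x[!is.na(x)]
  if (length(x) == 0) stopf("no intervals found in %s", path)
  rr_series(x)
}

#' Write peak annotations, one time in seconds per line
#' @param peaks An [r_peaks()] object.
#' @param path Output file path.
#' @export
write_peaks <- function(peaks, path) {
  writeLines(format(peaks$times, digits = 15, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Read peak annotations (one time in seconds per line)
#' @param path Input file path.
#' @return An [r_peaks()] object.
#' @export
read_peaks <- function(path) {
  x <- as.numeric(readLines(path))
  r_peaks(x[!is.na(x)])
}

#' Write a tidy group table as CSV
#' @param table A [group_table()].
#' @param path Output file path.
#' @export
write_group_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy group table from CSV
#' @param path Input file path (columns subject, group, metric, value).
#' @return A [group_table()].
#' @export
read_group_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  group_table(df$subject, df$group, df$metric, df$value)
}
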