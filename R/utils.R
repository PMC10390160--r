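# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)))
    stopf("`%s` must be a single finite number", name)
  if (!is.na(x) && (x < lower || x > upper))
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the current state is used (and advanced).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Extract normal (NN) intervals from an RR series
#'
#' Returns the intervals of `rr` whose normality flag is `TRUE`. Most
#' metric functions accept either a bare numeric vector of intervals in
#' milliseconds or an `rr_series`; this is the single place that applies
#' the ectopy flags set by [nn_filter()].
#'
#' @param rr An `rr_series` object or a numeric vector of RR intervals (ms).
#' @return Numeric vector of NN intervals in milliseconds.
#' @export
nn_intervals <- function(rr) {
  if (inherits(rr, "rr_series")) return(rr$intervals[rr$normal])
  if (is.numeric(rr)) return(as.numeric(rr))
  stopf("expected an `rr_series` or a numeric vector of intervals")
}
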