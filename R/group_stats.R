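# Group-comparison statistics: normality screening, two-group tests,
# one-way ANOVA, and inference from published mean/SD/n summaries.

significance_grade <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) return("***")
  if (p < 0.01) return("**")
  if (p < 0.05) return("*")
  "ns"
}

stat_result <- function(test, statistic, df, p, summaries = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p),
                 grade = significance_grade(unname(p)),
                 summaries = summaries),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g %s\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p, x$grade))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] returning the common
#' result container.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return A `stat_test_result` with W as the statistic.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3 || length(values) > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(values))
  sw <- stats::shapiro.test(values)
  stat_result("Shapiro-Wilk", sw$statistic, NA_real_, sw$p.value,
              summaries = list(n = length(values), mean = mean(values),
                               sd = stats::sd(values)))
}

#' Independent two-sample t test
#'
#' Two-sided; Welch degrees of freedom by default (`equal_var = FALSE`),
#' pooled-variance Student t when `equal_var = TRUE`.
#'
#' @param g1,g2 Numeric samples, each n >= 2.
#' @param equal_var Assume equal variances (default FALSE).
#' @return A `stat_test_result`.
#' @export
t_test_independent <- function(g1, g2, equal_var = FALSE) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) < 2 || length(g2) < 2) stopf("each group needs n >= 2")
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0 && mean(g1) == mean(g2))
    stopf("both groups constant and equal: t test undefined")
  tt <- stats::t.test(g1, g2, var.equal = equal_var)
  stat_result(ifelse(equal_var, "Student t (pooled)", "Welch t"),
              tt$statistic, tt$parameter, tt$p.value,
              summaries = list(
                g1 = c(mean = mean(g1), sd = stats::sd(g1), n = length(g1)),
                g2 = c(mean = mean(g2), sd = stats::sd(g2), n = length(g2))))
}

#' Welch t test from published mean/SD/n summaries
#'
#' Enables auditing printed group tables without raw data:
#' t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2), Welch-Satterthwaite
#' degrees of freedom, two-sided p.
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return A `stat_test_result`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (nm in c("n1", "n2")) check_number(get(nm), nm, lower = 2)
  for (nm in c("sd1", "sd2")) check_number(get(nm), nm, lower = 0)
  if (sd1 == 0 && sd2 == 0) stopf("at least one group must have positive SD")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  stat_result("Welch t (from summaries)", t, df, p,
              summaries = list(g1 = c(mean = mean1, sd = sd1, n = n1),
                               g2 = c(mean = mean2, sd = sd2, n = n2)))
}

#' One-way ANOVA
#'
#' Classical fixed-effects F test, F = MS_between / MS_within on
#' (k - 1, N - k) degrees of freedom, via
#' [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups A list of >= 3 numeric samples, each n >= 2.
#' @return A `stat_test_result`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stopf("one-way ANOVA requires at least 3 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stopf("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  aw <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  stat_result("One-way ANOVA", aw$statistic, aw$parameter, aw$p.value,
              summaries = lapply(groups, function(g)
                c(mean = mean(g), sd = stats::sd(g), n = length(g))))
}

#' Construct a tidy subjects-by-metrics group table
#'
#' @param subject,group,metric,value Equal-length vectors (long format).
#' @return A data frame of class `group_table`.
#' @export
group_table <- function(subject, group, metric, value) {
  df <- data.frame(subject = as.character(subject),
                   group = as.character(group),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  class(df) <- c("group_table", class(df))
  df
}

#' Compare groups metric by metric
#'
#' For every metric in the table: per-group mean +/- SD, per-group
#' Shapiro-Wilk screening, one-way ANOVA across all groups (when >= 3),
#' and all pairwise two-group tests (Welch by default; the study-style
#' independent t-test layer). Graded significance marks at the
#' 0.05/0.01/0.001 thresholds; no multiplicity correction by default,
#' Holm correction of the pairwise p values behind `correct = "holm"`.
#'
#' @param table A [group_table()] (or a data frame with columns
#'   subject, group, metric, value).
#' @param equal_var Use pooled-variance pairwise tests (default FALSE).
#' @param correct `"none"` (default) or `"holm"` for the pairwise p
#'   values within each metric.
#' @return A list of class `group_comparison`: one element per metric
#'   with `summary` (data frame), `shapiro`, `anova`, `pairwise`.
#' @export
compare_groups <- function(table, equal_var = FALSE,
                           correct = c("none", "holm")) {
  correct <- match.arg(correct)
  if (!all(c("subject", "group", "metric", "value") %in% names(table)))
    stopf("`table` needs columns subject, group, metric, value")
  groups <- unique(table$group)
  if (length(groups) < 2) stopf("need at least 2 groups to compare")

  out <- list()
  for (met in unique(table$metric)) {
    sub <- table[table$metric == met & is.finite(table$value), ]
    glists <- split(sub$value, sub$group)
    glists <- glists[vapply(glists, length, integer(1)) >= 2]
    if (length(glists) < 2) {
      warnf("metric '%s': fewer than 2 groups with n >= 2; summaries only", met)
    }
    summary_df <- do.call(rbind, lapply(names(glists), function(g)
      data.frame(group = g, n = length(glists[[g]]),
                 mean = mean(glists[[g]]), sd = stats::sd(glists[[g]]))))
    shap <- lapply(glists, function(v)
      if (length(v) >= 3) shapiro_wilk(v) else NULL)
    aov_res <- if (length(glists) >= 3) anova_oneway(glists) else NULL
    pw <- list()
    if (length(glists) >= 2) {
      cmb <- utils::combn(names(glists), 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        pw[[paste(a, b, sep = " vs ")]] <-
          t_test_independent(glists[[a]], glists[[b]], equal_var = equal_var)
      }
      if (correct == "holm" && length(pw) > 1) {
        padj <- stats::p.adjust(vapply(pw, `[[`, numeric(1), "p"), "holm")
        for (k in seq_along(pw)) {
          pw[[k]]$p_adjusted <- padj[k]
          pw[[k]]$grade <- significance_grade(padj[k])
        }
      }
    }
    out[[met]] <- list(summary = summary_df, shapiro = shap,
                       anova = aov_res, pairwise = pw)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (met in names(x)) {
    cat(sprintf("== %s ==\n", met))
    s <- x[[met]]$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-4s n=%d  %.3f +/- %.3f\n", s$group[i], s$n[i],
                  s$mean[i], s$sd[i]))
    if (!is.null(x[[met]]$anova))
      cat(sprintf("  ANOVA F = %.3f, p = %.4g %s\n", x[[met]]$anova$statistic,
                  x[[met]]$anova$p, x[[met]]$anova$grade))
    for (nm in names(x[[met]]$pairwise)) {
      pw <- x[[met]]$pairwise[[nm]]
      cat(sprintf("  %-12s t = %7.3f, p = %.4g %s\n", nm, pw$statistic,
                  pw$p, pw$grade))
    }
  }
  invisible(x)
}
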