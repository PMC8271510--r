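# Reliability and group-comparison statistics.

#' Summarise one group x pass-type cell
#'
#' @param mean,sd,n sample mean, standard deviation (>= 0) and size (>= 2).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0 || !is.finite(n) || n < 2) {
    stop_qpass("need finite mean, sd >= 0 and n >= 2",
               class = "qpass_input_error")
  }
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Standard error of measurement from a repeated-measures ANOVA
#'
#' Within-subject (test-retest) measurement error: the square root of the
#' mean-square error of the two-way subjects-by-trials decomposition,
#' `MS_error = SS_residual / ((s - 1)(t - 1))`. Subject effects are absorbed
#' by the subject term, so adding a subject-specific constant leaves the SEM
#' unchanged.
#'
#' @param data either a numeric matrix (rows = subjects, columns = trials)
#'   or a data.frame with columns `subject`, `trial`, `value` forming a
#'   complete design (every subject-trial cell exactly once).
#' @return the SEM (same units as the values).
#' @export
#' @examples
#' sem_repeated_measures(matrix(c(0, 0, 2, 0), nrow = 2)) # 1
sem_repeated_measures <- function(data) {
  if (is.matrix(data)) {
    if (anyNA(data)) {
      stop_qpass("design is incomplete (missing cells)",
                 class = "qpass_design_error")
    }
    data <- data.frame(
      subject = rep(seq_len(nrow(data)), times = ncol(data)),
      trial = rep(seq_len(ncol(data)), each = nrow(data)),
      value = as.numeric(data))
  }
  if (!is.data.frame(data) ||
      !all(c("subject", "trial", "value") %in% names(data))) {
    stop_qpass("data must be a matrix or a subject/trial/value data.frame",
               class = "qpass_input_error")
  }
  data$subject <- factor(data$subject)
  data$trial <- factor(data$trial)
  if (nlevels(data$subject) < 2L || nlevels(data$trial) < 2L) {
    stop_qpass("need at least 2 subjects and 2 trials",
               class = "qpass_input_error")
  }
  if (anyNA(data$value) ||
      any(table(data$subject, data$trial) != 1L)) {
    stop_qpass("design is incomplete (missing cells)",
               class = "qpass_design_error")
  }
  fit <- stats::lm(value ~ subject + trial, data = data)
  sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
}

#' Coefficient of variation in percent
#'
#' `sem / mean * 100`, the relative test-retest error of the score.
#'
#' @param sem standard error of measurement.
#' @param mean sample mean (non-zero).
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(2.9, 80.4) # about 3.6
cv_percent <- function(sem, mean) {
  if (any(mean == 0)) {
    stop_qpass("CV is undefined for a zero mean", class = "qpass_input_error")
  }
  sem / mean * 100
}

#' Hedge's g effect size between two groups
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled` with the
#' small-sample correction `J = 1 - 3 / (4 N - 9)` (set `exact = TRUE` for
#' the gamma-function form of `J`); `s_pooled` is the usual pooled standard
#' deviation with `n_a + n_b - 2` degrees of freedom.
#'
#' @param a,b [group_summary()] objects.
#' @param exact use the exact gamma-function small-sample correction.
#' @return Hedge's g (dimensionless; positive when `a` scores higher).
#' @export
#' @examples
#' hedges_g(group_summary(68.3, 6.5, 8), group_summary(61.1, 9.8, 8))
hedges_g <- function(a, b, exact = FALSE) {
  if (!inherits(a, "group_summary") || !inherits(b, "group_summary")) {
    stop_qpass("a and b must be group_summary objects",
               class = "qpass_input_error")
  }
  df <- a$n + b$n - 2L
  s_pooled <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df)
  if (s_pooled == 0) {
    if (a$mean == b$mean) return(0)
    stop_qpass("effect size undefined: zero pooled SD with unequal means",
               class = "qpass_undefined_effect_error")
  }
  J <- if (exact) {
    exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
  } else {
    1 - 3 / (4 * (a$n + b$n) - 9)
  }
  J * (a$mean - b$mean) / s_pooled
}

#' Two-sample Student's t mean difference with 95% CI
#'
#' Pooled-variance (equal-variance) Student's t-test; the confidence
#' interval is `diff +/- t_{0.975, df} * SE_diff`. Two zero-variance samples
#' are reported as an exact difference with a warning instead of a test.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param conf confidence level for the interval.
#' @return list with `mean_diff` (a minus b), `ci95` (length-2 vector), `p`,
#'   `t` and `df` (the latter three `NA` in the degenerate zero-variance
#'   case).
#' @export
ttest_mean_difference <- function(a, b, conf = 0.95) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_qpass("each sample needs at least 2 values",
               class = "qpass_input_error")
  }
  assert_finite(a, "a"); assert_finite(b, "b")
  d <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("both samples have zero variance; reporting the exact difference")
    return(list(mean_diff = d, ci95 = c(d, d), p = NA_real_, t = NA_real_,
                df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, conf.level = conf)
  list(mean_diff = d, ci95 = as.numeric(tt$conf.int), p = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Percent change between two group means
#'
#' `(a_mean - b_mean) / base * 100`. The base is configurable because
#' "x% greater" phrasing is ambiguous; the default base is the second
#' (typically lower-scoring) group.
#'
#' @param a_mean,b_mean group means.
#' @param base which mean to divide by: `"b"` (default) or `"a"`.
#' @return percent change.
#' @export
#' @examples
#' percent_change(110, 100) # 10
percent_change <- function(a_mean, b_mean, base = c("b", "a")) {
  base <- match.arg(base)
  denom <- if (base == "b") b_mean else a_mean
  if (any(denom == 0)) {
    stop_qpass("percent change is undefined for a zero base",
               class = "qpass_input_error")
  }
  (a_mean - b_mean) / denom * 100
}

#' Flag outliers by z-score
#'
#' Flags values whose absolute z-score against the sample mean and SD
#' exceeds the threshold. A zero-spread sample yields no flags, with a
#' warning.
#'
#' @param values numeric sample, length >= 3.
#' @param threshold absolute z-score cut-off (default 3).
#' @return logical vector of flags.
#' @export
zscore_outliers <- function(values, threshold = 3) {
  if (length(values) < 3L) {
    stop_qpass("need at least 3 values", class = "qpass_input_error")
  }
  assert_finite(values, "values")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  abs((values - mean(values)) / s) > threshold
}

#' Qualitative label of an effect size
#'
#' Thresholds on `|g|`: below 0.2 negligible, 0.2 small, 0.5 medium,
#' 0.8 large and 1.2 or more extra-large.
#'
#' @param g effect size(s).
#' @return character label(s).
#' @export
#' @examples
#' effect_label(c(0.58, 0.82, 1.91))
effect_label <- function(g) {
  if (any(!is.finite(g))) {
    stop_qpass("g must be finite", class = "qpass_input_error")
  }
  labs <- c("negligible", "small", "medium", "large", "extra-large")
  labs[findInterval(abs(g), c(0.2, 0.5, 0.8, 1.2)) + 1L]
}
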