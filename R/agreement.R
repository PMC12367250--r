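#' Intraclass correlation ICC(2,1): two-way random effects, absolute agreement
#'
#' Single-measure ICC from the two-way random-effects ANOVA decomposition with
#' `k = 2` raters (model and reference), absolute-agreement definition:
#' \deqn{ICC = \frac{MS_S - MS_E}{MS_S + (k-1) MS_E + \frac{k}{n}(MS_R - MS_E)}}
#' where `MS_S`, `MS_R`, `MS_E` are the subject, rater and residual mean
#' squares. Absolute agreement penalizes a systematic offset between raters,
#' unlike the consistency definition. The average-measure variant ICC(2,k) is
#' available behind `average = TRUE`.
#'
#' @param a,b paired measurements (model and reference), length `n >= 3`.
#' @param average report the average-measure ICC(2,k) instead.
#' @return ICC in `(-Inf, 1]`, or `NA` (with a warning) when the
#'   between-subject variance is zero.
#' @export
icc_2way_absolute <- function(a, b, average = FALSE) {
  stopifnot(length(a) == length(b), length(a) >= 3L,
            !anyNA(a), !anyNA(b))
  n <- length(a); k <- 2
  y <- cbind(a, b)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  rater_means <- colMeans(y)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  ms_s <- ss_subj / (n - 1)
  ms_r <- ss_rater / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_s < 1e-300) {
    warning("zero between-subject variance; ICC undefined")
    return(NA_real_)
  }
  if (average) {
    (ms_s - ms_e) / (ms_s + (ms_r - ms_e) / n)
  } else {
    (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + k / n * (ms_r - ms_e))
  }
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b` per subject; the bias is their mean and the 95%
#' limits of agreement are `bias +/- 1.96 * SD(differences)`. Per-subject
#' `(mean, difference)` coordinates are returned for plotting.
#'
#' @param a,b paired measurements, length `n >= 2`.
#' @return list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `points` (data.frame `mean`, `diff`), `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L, !anyNA(a), !anyNA(b))
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 points = data.frame(mean = (a + b) / 2, diff = d),
                 n = length(a)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Linear trend test of a measurement across ordinal grades
#'
#' Ordinary least squares of the measurement on the ordinal grade treated as
#' a continuous predictor, with a two-sided t-test on the slope.
#'
#' @param values numeric measurements (e.g. model IMAT percentages).
#' @param grades ordinal grades in `{0, 1, 2}` (any integer-valued grades
#'   work); at least 2 distinct grades must be present.
#' @return list with `slope`, `p_trend`, `n`.
#' @export
trend_test <- function(values, grades) {
  g <- as.numeric(grades)
  stopifnot(length(values) == length(g), length(values) >= 3L)
  if (length(unique(g)) < 2L) stop("at least 2 distinct grades required")
  fit <- stats::lm(values ~ g)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["g", "Estimate"]),
       p_trend = unname(sm["g", "Pr(>|t|)"]),
       n = length(values))
}

#' Independent two-sample t-test
#'
#' Welch's variant by default (`var_equal = FALSE`); the pooled-variance
#' Student variant is selectable. Two degenerate groups with zero variance
#' and equal means return `t = 0, p = 1` by convention.
#'
#' @param x,y the two samples, each of length >= 2.
#' @param var_equal use the pooled-variance test.
#' @return list with `t`, `p`.
#' @export
group_ttest <- function(x, y, var_equal = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Pearson product-moment correlation of paired measurements
#'
#' @param a,b paired measurements, length `n >= 3`, each with nonzero
#'   variance (zero variance gives `NA` with a warning).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Full agreement summary between two raters
#'
#' Pearson correlation, single-measure absolute-agreement ICC(2,1) and
#' Bland-Altman bias/limits for one feature measured by a model and a
#' reference rater.
#'
#' @param a,b paired measurements (model, reference), length `n >= 3`.
#' @return list of class `agreement_result`: `pearson_r`, `icc`,
#'   `bland_altman`, `n`.
#' @export
agreement_summary <- function(a, b) {
  structure(list(pearson_r = pearson(a, b),
                 icc = icc_2way_absolute(a, b),
                 bland_altman = bland_altman(a, b),
                 n = length(a)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement (n = %d): Pearson r = %.4f, ICC(2,1) = %.4f\n",
              x$n, x$pearson_r, x$icc))
  print(x$bland_altman)
  invisible(x)
}
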