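#' Absolute percent error between estimated and measured values
#'
#' Per subject, `|estimate - measured| / measured * 100`; summarised by the
#' mean and its t-based 95% confidence interval. Subjects with a measured
#' value of zero cannot be expressed in percent and are excluded with a
#' warning.
#'
#' @param estimates An `estimate_set` (or numeric vector) of calibrated
#'   XCTII* values.
#' @param measured Numeric vector of measured XCTII values, same order/length.
#' @return Object of class `percent_error_summary`: `errors` (per-subject,
#'   percent), `mean`, `ci_low`, `ci_high`, `n`.
#' @export
percent_error <- function(estimates, measured) {
  est <- if (inherits(estimates, "estimate_set")) estimates$estimates else estimates
  if (length(est) != length(measured))
    stop("estimates and measured values must pair up")
  ok <- !is.na(est) & !is.na(measured)
  est <- est[ok]; measured <- measured[ok]
  if (any(measured == 0)) {
    warning(sum(measured == 0), " subject(s) with measured value 0 excluded")
    keep <- measured != 0
    est <- est[keep]; measured <- measured[keep]
  }
  n <- length(est)
  if (n < 2) stop("need at least 2 paired values")
  errs <- abs(est - measured) / abs(measured) * 100
  m <- mean(errs)
  se <- sd(errs) / sqrt(n)
  half <- qt(0.975, n - 1) * se
  structure(list(errors = errs, mean = m, ci_low = m - half,
                 ci_high = m + half, n = n),
            class = "percent_error_summary")
}

#' @export
print.percent_error_summary <- function(x, ...) {
  cat(sprintf("mean absolute percent error %.2f%% (95%% CI %.2f, %.2f), n = %d\n",
              x$mean, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` against means `(a + b) / 2`: mean difference, 95%
#' limits of agreement (mean +/- 1.96 SD of the differences), and
#' proportional bias assessed by ordinary least squares of the differences on
#' the means (slope and its two-sided p-value). With constant means the
#' proportional-bias regression does not exist and is flagged `NA`.
#'
#' @param a,b Paired numeric vectors (>= 3 pairs).
#' @return Object of class `bland_altman_result`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must pair up")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- sd(d)
  slope <- NA_real_; pval <- NA_real_
  if (var(m) > 0) {
    fit <- ols_fit(m, d)
    slope <- fit["slope"]
    n <- length(d)
    res <- d - (fit["intercept"] + slope * m)
    dfree <- n - 2
    se <- sqrt(sum(res^2) / dfree / sum((m - mean(m))^2))
    pval <- if (se == 0) { if (abs(slope) > 0) 0 else 1 }
            else 2 * pt(-abs(slope / se), dfree)
  } else warning("constant means: proportional bias undefined")
  structure(list(mean_difference = md, loa_low = md - 1.96 * sdd,
                 loa_high = md + 1.96 * sdd, sd_difference = sdd,
                 prop_bias_slope = unname(slope), prop_bias_p = unname(pval),
                 n = length(d), differences = d, means = m),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4f, 95%% LoA [%.4f, %.4f], n = %d\n",
              x$mean_difference, x$loa_low, x$loa_high, x$n))
  if (!is.na(x$prop_bias_slope))
    cat(sprintf("  proportional bias slope %.4f (p = %.3g)\n",
                x$prop_bias_slope, x$prop_bias_p))
  invisible(x)
}

#' Classify cross-scanner correlation strength
#'
#' Strong for R-squared above 0.9, moderate between 0.7 and 0.9, weak below
#' 0.7. The class bounds are open intervals; a value falling exactly on a
#' boundary is assigned to the lower class with a warning.
#'
#' @param r_squared R-squared in [0, 1].
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_correlation <- function(r_squared) {
  if (is.na(r_squared) || r_squared < 0 || r_squared > 1)
    stop("r_squared must lie in [0, 1]")
  if (r_squared %in% c(0.7, 0.9))
    warning("R-squared exactly on a class boundary (open intervals); assigned to the lower class")
  if (r_squared > 0.9) "strong" else if (r_squared > 0.7) "moderate" else "weak"
}

#' Compare per-subject percent errors of two analysis methods
#'
#' Two-sided paired t-test on the per-subject absolute percent errors of the
#' standard and Laplace-Hamming pipelines. Zero-variance differences are
#' handled in the limit: identical error vectors give p = 1, a constant
#' nonzero shift gives p = 0.
#'
#' @param errors_standard,errors_lh `percent_error_summary` objects (or
#'   numeric vectors) paired by subject.
#' @return Two-sided p-value.
#' @export
compare_methods <- function(errors_standard, errors_lh) {
  e1 <- if (inherits(errors_standard, "percent_error_summary"))
    errors_standard$errors else errors_standard
  e2 <- if (inherits(errors_lh, "percent_error_summary"))
    errors_lh$errors else errors_lh
  if (length(e1) != length(e2))
    stop("error vectors must be paired by subject")
  d <- e1 - e2
  n <- length(d)
  if (n < 2) stop("need at least 2 paired error values")
  sdd <- sd(d)
  if (sdd == 0) return(if (mean(d) == 0) 1 else 0)
  tstat <- mean(d) / (sdd / sqrt(n))
  2 * pt(-abs(tstat), n - 1)
}
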