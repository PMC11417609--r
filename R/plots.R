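#' Bland-Altman plot
#'
#' Differences against means with the mean difference (solid) and the 95%
#' limits of agreement (dashed).
#'
#' @param ba A `bland_altman_result`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = "Bland-Altman") {
  stopifnot(inherits(ba, "bland_altman_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(mean = ba$means, diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_difference) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of methods",
                  y = "Difference between methods") +
    ggplot2::theme_minimal()
}

#' Calibration scatter plot
#'
#' Training pairs with the averaged bootstrap regression line and the line of
#' unity.
#'
#' @param pair Cohort pair (see [generate_paired_cohort()]).
#' @param eq A `calibration_equation`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(pair, eq) {
  stopifnot(inherits(eq, "calibration_equation"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  pv <- paired_values(pair, eq$parameter)
  df <- data.frame(xcti = pv$x, xctii = pv$y)
  ggplot2::ggplot(df, ggplot2::aes(x = xcti, y = xctii)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = eq$slope, intercept = eq$intercept) +
    ggplot2::labs(title = sprintf("%s: XCTII = %.3f XCTI + %.3f (R2 = %.2f)",
                                  eq$parameter, eq$slope, eq$intercept,
                                  eq$r_squared),
                  x = "XCTI", y = "XCTII") +
    ggplot2::theme_minimal()
}
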