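#' Specify a measurement-level paired cohort simulation
#'
#' Emulates the statistical structure of a paired two-scanner study at the
#' outcome level (no imaging): for each subject, the first-generation (XCTI)
#' value of a parameter is drawn from a normal distribution, and the
#' second-generation (XCTII) value is a linear function of it plus noise on
#' the XCTII side only (matching the XCTI -> XCTII estimation direction of
#' the cross-calibration).
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param parameters Data frame with columns `parameter`, `true_slope`,
#'   `true_intercept`, `xcti_mean`, `xcti_sd`, `noise_sd`.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects, parameters, seed = 1L) {
  parameters <- as.data.frame(parameters)
  need <- c("parameter", "true_slope", "true_intercept", "xcti_mean",
            "xcti_sd", "noise_sd")
  if (!all(need %in% names(parameters)))
    stop("parameters must have columns: ", paste(need, collapse = ", "))
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (any(parameters$xcti_sd <= 0)) stop("xcti_sd must be > 0")
  if (any(parameters$noise_sd < 0)) stop("noise_sd must be >= 0")
  bad <- setdiff(parameters$parameter, .param_levels)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.param_levels, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects), parameters = parameters,
                 seed = as.integer(seed)), class = "cohort_sim_spec")
}

#' Noise level yielding a target population R-squared
#'
#' For `y = slope * x + intercept + e` with `x ~ N(m, xcti_sd^2)` and
#' `e ~ N(0, noise_sd^2)`, the population R-squared is
#' `slope^2 xcti_sd^2 / (slope^2 xcti_sd^2 + noise_sd^2)`; this inverts that
#' relation.
#'
#' @param slope,xcti_sd Simulation parameters.
#' @param r2 Target population R-squared in (0, 1].
#' @return Noise standard deviation.
#' @export
noise_sd_for_r2 <- function(slope, xcti_sd, r2) {
  stopifnot(r2 > 0, r2 <= 1)
  abs(slope) * xcti_sd * sqrt((1 - r2) / r2)
}

#' Generate a paired measurement-level cohort
#'
#' @param spec A `cohort_sim_spec`.
#' @param method Analysis method label recorded in the tables.
#' @return List with outcome tables `xcti` and `xctii` (data frames with
#'   columns `subject_id`, `parameter`, `scanner`, `method`, `value`,
#'   `units`).
#' @export
generate_paired_cohort <- function(spec, method = "standard") {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  rows_x <- list(); rows_y <- list()
  for (k in seq_len(nrow(spec$parameters))) {
    p <- spec$parameters[k, ]
    x <- rnorm(n, p$xcti_mean, p$xcti_sd)
    e <- if (p$noise_sd > 0) rnorm(n, 0, p$noise_sd) else numeric(n)
    y <- p$true_slope * x + p$true_intercept + e
    un <- unname(.param_units[p$parameter])
    rows_x[[k]] <- data.frame(subject_id = ids, parameter = p$parameter,
                              scanner = "XCTI", method = method, value = x,
                              units = un, stringsAsFactors = FALSE)
    rows_y[[k]] <- data.frame(subject_id = ids, parameter = p$parameter,
                              scanner = "XCTII", method = method, value = y,
                              units = un, stringsAsFactors = FALSE)
  }
  list(xcti = do.call(rbind, rows_x), xctii = do.call(rbind, rows_y))
}
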