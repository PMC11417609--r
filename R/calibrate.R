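#' Randomly split a cohort into training and test sets
#'
#' Uniform random partition of the subjects without replacement; by default
#' 12 subjects are set aside for validation and the rest train the
#' calibration.
#'
#' @param table An outcome table (data frame with `subject_id`) or a
#'   character vector of subject ids.
#' @param n_test Number of test subjects (>= 2, < cohort size).
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return Object of class `split_plan`: list with `training_ids`,
#'   `test_ids`, `seed`.
#' @export
split_cohort <- function(table, n_test = 12, seed = 1L) {
  ids <- if (is.character(table)) unique(table) else unique(table$subject_id)
  if (n_test < 2) stop("n_test must be >= 2")
  if (n_test >= length(ids))
    stop("n_test must be smaller than the cohort size (training set would be empty)")
  set.seed(as.integer(seed))
  test <- sort(sample(ids, n_test))
  structure(list(training_ids = setdiff(ids, test), test_ids = test,
                 seed = as.integer(seed)), class = "split_plan")
}

# Closed-form simple OLS of y on x; returns slope, intercept, r2.
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ssr <- sum((y - slope * x - intercept)^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else if (ssr <= 1e-24) 1 else 0
  c(slope = slope, intercept = intercept, r2 = max(0, min(1, r2)))
}

# Extract paired (x, y) vectors for one parameter from a cohort pair,
# dropping subjects with a missing value on either side.
paired_values <- function(pair, parameter, ids = NULL) {
  gx <- pair$xcti[pair$xcti$parameter == parameter, c("subject_id", "value")]
  gy <- pair$xctii[pair$xctii$parameter == parameter, c("subject_id", "value")]
  m <- merge(gx, gy, by = "subject_id", suffixes = c("_x", "_y"))
  if (!is.null(ids)) m <- m[m$subject_id %in% ids, ]
  keep <- !is.na(m$value_x) & !is.na(m$value_y)
  n_dropped <- sum(!keep)
  m <- m[keep, ]
  m <- m[order(m$subject_id), ]
  list(id = m$subject_id, x = m$value_x, y = m$value_y, n_dropped = n_dropped)
}

#' Bootstrap cross-calibration of one outcome parameter
#'
#' Repeats `n_boot` times: draw `draw_size` training pairs with replacement,
#' fit ordinary least squares `XCTII = slope * XCTI + intercept`, record
#' slope, intercept and R-squared. The reported equation is the arithmetic
#' mean of each quantity over the iterations. Degenerate draws (all XCTI
#' values identical, so no regression exists) are redrawn and counted, which
#' keeps exactly `n_boot` retained fits with uniform weight.
#'
#' @param pair List with outcome tables `xcti` and `xctii`
#'   (see [generate_paired_cohort()]).
#' @param parameter Outcome parameter name.
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param draw_size Pairs drawn per iteration (default 12).
#' @param seed Integer seed; fixes all draws bit-exactly.
#' @param training_ids Optional subject ids restricting the training pool.
#' @return Object of class `calibration_equation`.
#' @export
bootstrap_calibrate <- function(pair, parameter, n_boot = 1000, draw_size = 12,
                                seed = 1L, training_ids = NULL) {
  pv <- paired_values(pair, parameter, training_ids)
  n <- length(pv$x)
  if (n < 2 || length(unique(pv$x)) < 2)
    stop("no variance for regression: need >= 2 distinct training points")
  set.seed(as.integer(seed))
  slopes <- numeric(n_boot); intercepts <- numeric(n_boot); r2s <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, draw_size, replace = TRUE)
      if (length(unique(pv$x[idx])) >= 2) break
      n_redrawn <- n_redrawn + 1L
    }
    fit <- ols_fit(pv$x[idx], pv$y[idx])
    slopes[b] <- fit["slope"]; intercepts[b] <- fit["intercept"]
    r2s[b] <- fit["r2"]
  }
  structure(list(parameter = parameter,
                 slope = mean(slopes), intercept = mean(intercepts),
                 r_squared = mean(r2s), n_boot = as.integer(n_boot),
                 draw_size = as.integer(draw_size),
                 boot_slopes = slopes, boot_intercepts = intercepts,
                 boot_r2 = r2s, seed = as.integer(seed),
                 n_train = n, n_redrawn = n_redrawn,
                 n_dropped = pv$n_dropped),
            class = "calibration_equation")
}

#' @export
print.calibration_equation <- function(x, ...) {
  cat(sprintf("calibration_equation %s: XCTII* = %.4f * XCTI + %.4f (R2 = %.3f)\n",
              x$parameter, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d bootstrap draws of %d from %d training pairs (%d redrawn, %d dropped)\n",
              x$n_boot, x$draw_size, x$n_train, x$n_redrawn, x$n_dropped))
  invisible(x)
}

#' Apply a calibration equation to first-generation values
#'
#' @param eq A `calibration_equation`.
#' @param xcti_values Numeric vector (possibly named by subject) of XCTI
#'   measurements; missing values propagate.
#' @return Object of class `estimate_set`: list with `parameter`,
#'   `estimates` and the source equation.
#' @export
apply_calibration <- function(eq, xcti_values) {
  stopifnot(inherits(eq, "calibration_equation"))
  if (!is.finite(eq$slope) || !is.finite(eq$intercept))
    stop("calibration equation is not finite")
  structure(list(parameter = eq$parameter,
                 estimates = eq$slope * xcti_values + eq$intercept,
                 equation = eq),
            class = "estimate_set")
}

#' Calibrate every parameter of a cohort pair
#'
#' Convenience wrapper running [bootstrap_calibrate()] over all parameters
#' present in the pair.
#'
#' @inheritParams bootstrap_calibrate
#' @param parameters Parameter names (default: all in the pair).
#' @return Named list of `calibration_equation`s.
#' @export
calibrate_all <- function(pair, parameters = NULL, n_boot = 1000,
                          draw_size = 12, seed = 1L, training_ids = NULL) {
  if (is.null(parameters)) parameters <- unique(pair$xcti$parameter)
  eqs <- lapply(seq_along(parameters), function(i)
    bootstrap_calibrate(pair, parameters[i], n_boot = n_boot,
                        draw_size = draw_size, seed = seed + i - 1L,
                        training_ids = training_ids))
  names(eqs) <- parameters
  eqs
}

#' Tabulate calibration equations
#'
#' @param eqs List of `calibration_equation`s.
#' @return Data frame with columns `parameter`, `slope`, `intercept`,
#'   `r_squared`, `n_boot`, `n_train`, mirroring the usual reporting layout.
#' @export
equations_table <- function(eqs) {
  do.call(rbind, lapply(eqs, function(e)
    data.frame(parameter = e$parameter, slope = e$slope,
               intercept = e$intercept, r_squared = e$r_squared,
               n_boot = e$n_boot, n_train = e$n_train,
               stringsAsFactors = FALSE)))
}
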