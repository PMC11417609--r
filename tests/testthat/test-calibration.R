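make_pair <- function(n = 36, slope = 1.66, intercept = 0.01, noise = 0,
                      seed = 2, parameter = "BV/TV", mean = 0.15, sd = 0.04) {
  pars <- data.frame(parameter = parameter, true_slope = slope,
                     true_intercept = intercept, xcti_mean = mean,
                     xcti_sd = sd, noise_sd = noise)
  generate_paired_cohort(cohort_sim_spec(n, pars, seed = seed))
}

test_that("cohort splits partition the subjects reproducibly", {
  co <- make_pair(36)
  p1 <- split_cohort(co$xcti, n_test = 12, seed = 4)
  p2 <- split_cohort(co$xcti, n_test = 12, seed = 4)
  expect_identical(p1, p2)
  expect_length(p1$test_ids, 12)
  expect_length(p1$training_ids, 24)
  expect_length(intersect(p1$test_ids, p1$training_ids), 0)
  expect_setequal(c(p1$test_ids, p1$training_ids), unique(co$xcti$subject_id))
  expect_error(split_cohort(co$xcti, n_test = 36), "smaller than the cohort")
})

test_that("a noise-free line is recovered exactly in every bootstrap iteration", {
  co <- make_pair(36, slope = 2, intercept = 1, mean = 10, sd = 3)
  eq <- bootstrap_calibrate(co, "BV/TV", n_boot = 500, draw_size = 12, seed = 7)
  expect_equal(eq$slope, 2, tolerance = 1e-12)
  expect_equal(eq$intercept, 1, tolerance = 1e-12)
  expect_true(all(abs(eq$boot_slopes - 2) < 1e-10))
  expect_true(all(eq$boot_r2 == 1))
})

test_that("simulated regression regimes are recovered within 5%", {
  # density-like regime: slope near one, large negative intercept, low noise
  slopes <- vapply(1:10, function(r) {
    co <- make_pair(36, slope = 1.03, intercept = -3.07, parameter = "Tt.BMD",
                    mean = 300, sd = 60,
                    noise = noise_sd_for_r2(1.03, 60, 0.95), seed = 100 + r)
    bootstrap_calibrate(co, "Tt.BMD", n_boot = 200, draw_size = 12,
                        seed = r)$slope
  }, numeric(1))
  expect_equal(mean(slopes), 1.03, tolerance = 0.05)
})

test_that("degenerate draws are redrawn, keeping n_boot retained fits", {
  # two distinct x values only: draws hitting a single value must be redrawn
  xct <- data.frame(subject_id = c("a", "b"), parameter = "BV/TV",
                    scanner = "XCTI", method = "standard", value = c(1, 2),
                    units = "-")
  yct <- xct; yct$scanner <- "XCTII"; yct$value <- c(2, 4)
  pair <- list(xcti = xct, xctii = yct)
  eq <- bootstrap_calibrate(pair, "BV/TV", n_boot = 200, draw_size = 2,
                            seed = 1)
  expect_gt(eq$n_redrawn, 0)
  expect_length(eq$boot_slopes, 200)
  expect_true(all(is.finite(eq$boot_slopes)))
})

test_that("regression without x variance is refused", {
  xct <- data.frame(subject_id = c("a", "b", "c"), parameter = "BV/TV",
                    scanner = "XCTI", method = "standard", value = c(1, 1, 1),
                    units = "-")
  yct <- xct; yct$value <- c(1, 2, 3)
  expect_error(bootstrap_calibrate(list(xcti = xct, xctii = yct), "BV/TV"),
               "no variance")
})

test_that("full-size resamples converge to the full-sample OLS fit", {
  co <- make_pair(24, slope = 0.8, intercept = 5, parameter = "Ct.BMD",
                  mean = 900, sd = 80, noise = noise_sd_for_r2(0.8, 80, 0.9))
  pv <- bonexcal:::paired_values(co, "Ct.BMD")
  full <- unname(coef(lm(pv$y ~ pv$x)))
  eq <- bootstrap_calibrate(co, "Ct.BMD", n_boot = 5000, draw_size = 24,
                            seed = 11)
  # bootstrap mean approaches the full-sample fit within Monte-Carlo error
  boot_se <- sd(eq$boot_slopes) / sqrt(eq$n_boot)
  expect_lt(abs(eq$slope - full[2]), 4 * boot_se + 0.002)
})

test_that("equations are deterministic given the seed and average their arrays", {
  co <- make_pair(30, noise = 0.01)
  e1 <- bootstrap_calibrate(co, "BV/TV", n_boot = 300, seed = 5)
  e2 <- bootstrap_calibrate(co, "BV/TV", n_boot = 300, seed = 5)
  expect_identical(e1$boot_slopes, e2$boot_slopes)
  expect_equal(e1$slope, mean(e1$boot_slopes))
  expect_equal(e1$intercept, mean(e1$boot_intercepts))
  expect_equal(e1$r_squared, mean(e1$boot_r2))
})

test_that("calibration equations apply linearly and propagate missing values", {
  co <- make_pair(36, slope = 2, intercept = 1, mean = 10, sd = 3)
  eq <- bootstrap_calibrate(co, "BV/TV", n_boot = 50, seed = 3)
  est <- apply_calibration(eq, c(300, NA, 0.10))
  expect_equal(est$estimates, c(2 * 300 + 1, NA, 2 * 0.10 + 1))
  # radius total-density style coefficients: 1.03 * 300 - 3.07
  eq$slope <- 1.03; eq$intercept <- -3.07
  expect_equal(apply_calibration(eq, 300)$estimates, 305.93)
  eq$slope <- 0.23; eq$intercept <- 0
  expect_equal(apply_calibration(eq, 0.10)$estimates, 0.023)
})

test_that("missing outcome values are dropped pairwise and counted", {
  co <- make_pair(12, noise = 0.01)
  co$xctii$value[3] <- NA
  eq <- bootstrap_calibrate(co, "BV/TV", n_boot = 20, seed = 2)
  expect_equal(eq$n_train, 11)
  expect_equal(eq$n_dropped, 1)
})
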