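full_mask <- function(d, vox) binary_volume(array(TRUE, d), vox)

test_that("fixed-threshold limits behave on constant volumes", {
  d <- c(12, 12, 12)
  hi <- image_volume(array(800, d), 61)
  lo <- image_volume(array(0, d), 61)
  m <- full_mask(d, 61)
  expect_true(all(gaussian_binarize(hi, m, compartment = "trabecular")$voxels))
  expect_false(any(gaussian_binarize(lo, m, compartment = "trabecular")$voxels))
})

test_that("an uncalibrated volume cannot be BMD-thresholded", {
  v <- image_volume(array(500, c(10, 10, 10)), 61, calibrated = FALSE)
  expect_error(gaussian_binarize(v, full_mask(c(10, 10, 10), 61)),
               "BMD calibration required")
})

test_that("with vanishing smoothing the Gaussian method reduces to direct thresholding", {
  d <- c(16, 16, 16)
  arr <- array(100, d); arr[9:16, , ] <- 600
  v <- image_volume(arr, 61)
  b <- gaussian_binarize(v, full_mask(d, 61),
                         gaussian_seg_params(sigma_voxels = 0.2,
                                             support_voxels = 1),
                         "trabecular")
  direct <- arr >= 320
  away_from_interface <- !(slice.index(arr, 1) %in% 8:9)
  expect_true(all(b$voxels[away_from_interface] == direct[away_from_interface]))
})

test_that("both binarizers stay inside the compartment mask and the Gaussian one is threshold-monotone", {
  set.seed(21)
  d <- c(16, 16, 16)
  v <- image_volume(array(400 + 200 * rnorm(prod(d)), d), 61)
  m <- binary_volume(array(runif(prod(d)) < 0.7, d), 61)
  blo <- gaussian_binarize(v, m, gaussian_seg_params(threshold_trab_mgHA = 300),
                           "trabecular")
  bhi <- gaussian_binarize(v, m, gaussian_seg_params(threshold_trab_mgHA = 450,
                                                     threshold_cort_mgHA = 450),
                           "trabecular")
  blh <- laplace_hamming_binarize(v, m)
  expect_true(all(blo$voxels <= m$voxels))
  expect_true(all(blh$voxels <= m$voxels))
  expect_true(all(bhi$voxels <= blo$voxels))
})

test_that("a constant volume under the pure Laplacian yields an empty mask with a warning", {
  d <- c(12, 12, 12)
  v <- image_volume(array(700, d), 61)
  expect_warning(
    b <- laplace_hamming_binarize(v, full_mask(d, 61),
                                  lh_seg_params(epsilon_laplace_weight = 1)),
    "degenerate")
  expect_false(any(b$voxels))
})

test_that("the frequency-domain filter matches direct circular convolution", {
  d <- c(16, 16, 16)
  params <- lh_seg_params()
  H <- oracle_lh_response(d, params$hamming_cutoff_fraction,
                          params$epsilon_laplace_weight)
  kern <- Re(fft(H, inverse = TRUE)) / prod(d)
  set.seed(3)
  x <- array(rnorm(prod(d), 500, 150), d)
  direct <- oracle_circular_convolution(x, kern)
  filtered <- bonexcal:::lh_filter(x, params$hamming_cutoff_fraction,
                                   params$epsilon_laplace_weight)
  expect_equal(filtered, direct, tolerance = 1e-8)
  # impulse response equals the inverse transform of the designed window
  imp <- array(0, d); imp[1, 1, 1] <- 1
  expect_equal(bonexcal:::lh_filter(imp, params$hamming_cutoff_fraction,
                                    params$epsilon_laplace_weight),
               kern, tolerance = 1e-10)
})

test_that("Laplace-Hamming segmentation commutes with circular translation", {
  d <- c(16, 16, 16)
  set.seed(8)
  arr <- array(rnorm(prod(d), 400, 200), d)
  v <- image_volume(arr, 61)
  m <- full_mask(d, 61)
  b0 <- laplace_hamming_binarize(v, m)$voxels
  sh <- c(3, 5, 7)
  shifted <- arr[c((sh[1] + 1):d[1], 1:sh[1]),
                 c((sh[2] + 1):d[2], 1:sh[2]),
                 c((sh[3] + 1):d[3], 1:sh[3])]
  b1 <- laplace_hamming_binarize(image_volume(shifted, 61), m)$voxels
  b0s <- b0[c((sh[1] + 1):d[1], 1:sh[1]),
            c((sh[2] + 1):d[2], 1:sh[2]),
            c((sh[3] + 1):d[3], 1:sh[3])]
  expect_identical(b1, b0s)
})

test_that("fine features survive LH but not Gaussian smoothing with a half-density threshold", {
  # 2-voxel and 6-voxel plates at 700 mgHA: heavy Gaussian smoothing pushes
  # the thin plate under the 0.5 x density threshold, the Laplacian term of
  # the LH filter boosts and keeps it
  n <- 24
  arr <- array(0, c(n, n, n))
  arr[6:7, , ] <- 700
  arr[14:19, , ] <- 700
  v <- image_volume(arr, 61)
  m <- full_mask(c(n, n, n), 61)
  g <- gaussian_binarize(v, m,
                         gaussian_seg_params(sigma_voxels = 1.5,
                                             support_voxels = 3,
                                             threshold_trab_mgHA = 350,
                                             threshold_cort_mgHA = 350),
                         "trabecular")
  l <- laplace_hamming_binarize(v, m)
  expect_equal(sum(g$voxels[6:7, , ]), 0)          # thin plate lost
  expect_equal(sum(l$voxels[6:7, , ]), 2 * n * n)  # thin plate kept
  expect_gt(sum(g$voxels[14:19, , ]), 0.9 * 6 * n * n)
  expect_gt(sum(l$voxels[14:19, , ]), 0.9 * 6 * n * n)
})
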