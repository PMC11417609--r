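#' Parameters for Gaussian-filter binarization
#'
#' The standard second-generation protocol: a small truncated Gaussian
#' smoothing filter followed by fixed volumetric BMD thresholds, one per
#' compartment. Defaults follow conventional second-generation practice
#' (sigma 0.8 voxels, support 1 voxel, 320 mgHA/cm3 trabecular and 450
#' mgHA/cm3 cortical thresholds) and are fully configurable.
#'
#' @param sigma_voxels Gaussian sigma in voxels (> 0).
#' @param support_voxels Kernel truncation half-width in voxels.
#' @param threshold_trab_mgHA,threshold_cort_mgHA Fixed BMD thresholds.
#' @return An object of class `gaussian_seg_params`.
#' @export
gaussian_seg_params <- function(sigma_voxels = 0.8, support_voxels = 1,
                                threshold_trab_mgHA = 320,
                                threshold_cort_mgHA = 450) {
  if (sigma_voxels <= 0) stop("sigma_voxels must be > 0")
  if (threshold_trab_mgHA <= 0 || threshold_cort_mgHA <= 0)
    stop("thresholds must be > 0")
  if (threshold_cort_mgHA < threshold_trab_mgHA)
    stop("cortical threshold must be >= trabecular threshold")
  structure(list(sigma_voxels = sigma_voxels,
                 support_voxels = as.integer(support_voxels),
                 threshold_trab_mgHA = threshold_trab_mgHA,
                 threshold_cort_mgHA = threshold_cort_mgHA),
            class = "gaussian_seg_params")
}

#' Parameters for Laplace-Hamming binarization
#'
#' The first-generation-style protocol: a frequency-domain filter combining a
#' Laplacian edge-enhancement term with a Hamming low-pass window, followed by
#' a fixed global threshold expressed as a fraction of the filtered image's
#' in-mask positive range (the Laplacian term destroys the density scale, so
#' an absolute BMD threshold would be meaningless after filtering).
#'
#' @param hamming_cutoff_fraction Low-pass cutoff as a fraction of the radial
#'   Nyquist frequency, in (0, 1].
#' @param threshold_fraction Global threshold as a fraction of the filtered
#'   in-mask positive maximum, in (0, 1).
#' @param epsilon_laplace_weight Blend weight between the original image
#'   (weight 0) and its Laplacian (weight 1).
#' @return An object of class `lh_seg_params`.
#' @export
lh_seg_params <- function(hamming_cutoff_fraction = 0.8,
                          threshold_fraction = 0.4,
                          epsilon_laplace_weight = 0.5) {
  if (hamming_cutoff_fraction <= 0 || hamming_cutoff_fraction > 1)
    stop("hamming_cutoff_fraction must lie in (0, 1]")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (epsilon_laplace_weight < 0 || epsilon_laplace_weight > 1)
    stop("epsilon_laplace_weight must lie in [0, 1]")
  structure(list(hamming_cutoff_fraction = hamming_cutoff_fraction,
                 threshold_fraction = threshold_fraction,
                 epsilon_laplace_weight = epsilon_laplace_weight),
            class = "lh_seg_params")
}

# Truncated discrete Gaussian smoothing, separable, mirrored edges.
gauss_smooth3d <- function(arr, sigma_vox, support_vox) {
  s <- max(1L, as.integer(support_vox))
  k <- exp(-((-s:s)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  for (axis in 1:3) arr <- conv_axis_mirror(arr, k, axis)
  arr
}

conv_axis_mirror <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  s <- (length(k) - 1L) / 2L
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - s - 1L
    id <- seq_len(n) + off
    id[id < 1L] <- 2L - id[id < 1L]
    id[id > n] <- 2L * n - id[id > n]
    shifted <- switch(axis,
                      arr[id, , , drop = FALSE],
                      arr[, id, , drop = FALSE],
                      arr[, , id, drop = FALSE])
    out <- out + k[j] * shifted
  }
  out
}

#' Gaussian-filter binarization with fixed BMD thresholds
#'
#' @param vol Calibrated `image_volume` (mgHA/cm3).
#' @param mask `binary_volume` compartment mask on the same grid.
#' @param params A `gaussian_seg_params`.
#' @param compartment `"trabecular"` or `"cortical"`, selecting the
#'   threshold.
#' @return A `binary_volume`; always a subset of `mask`.
#' @export
gaussian_binarize <- function(vol, mask, params = gaussian_seg_params(),
                              compartment = c("trabecular", "cortical")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_volume"))
  if (!vol$calibrated) stop("BMD calibration required")
  if (!identical(dim(vol$data), dim(mask$voxels)))
    stop("mask grid does not match the volume")
  thr <- if (compartment == "trabecular") params$threshold_trab_mgHA
         else params$threshold_cort_mgHA
  sm <- gauss_smooth3d(vol$data, params$sigma_voxels, params$support_voxels)
  binary_volume(sm >= thr & mask$voxels, vol$voxel_um)
}

# Frequency response of the Laplace-Hamming filter on a grid of dims d:
# H(f) = [(1 - w) + w * Lap(f)] * W(rho), with Lap the exact response of the
# (negated) discrete 6-neighbour Laplacian, rho = |f| / f_Nyquist, and W a
# Hamming window vanishing at the cutoff.
lh_response <- function(d, cutoff, weight) {
  f1 <- fft_freq(d[1]); f2 <- fft_freq(d[2]); f3 <- fft_freq(d[3])
  lap1 <- 4 * sin(pi * f1)^2; lap2 <- 4 * sin(pi * f2)^2
  lap3 <- 4 * sin(pi * f3)^2
  r1 <- (f1 / 0.5)^2; r2 <- (f2 / 0.5)^2; r3 <- (f3 / 0.5)^2
  add3 <- function(a, b, c) {
    out <- array(a, d)
    out <- out + rep(b, each = d[1])
    out + rep(c, each = d[1] * d[2])
  }
  lap <- add3(lap1, lap2, lap3)
  rho <- sqrt(add3(r1, r2, r3)) / sqrt(3)   # radial fraction of Nyquist
  W <- ifelse(rho <= cutoff, 0.54 + 0.46 * cos(pi * rho / cutoff), 0)
  ((1 - weight) + weight * lap) * W
}

# Apply the LH filter (mirror padding to even sizes, FFT, crop back).
lh_filter <- function(arr, cutoff, weight) {
  d <- dim(arr)
  if (any(d < 8)) stop("volume must be at least 8 voxels along every axis")
  pad <- d %% 2L
  if (any(pad == 1L)) {
    dp <- d + pad
    padded <- array(0, dp)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    if (pad[1]) padded[dp[1], , ] <- padded[d[1], , ]
    if (pad[2]) padded[, dp[2], ] <- padded[, d[2], ]
    if (pad[3]) padded[, , dp[3]] <- padded[, , d[3]]
    arr <- padded
  }
  H <- lh_response(dim(arr), cutoff, weight)
  out <- Re(fft(fft(arr) * H, inverse = TRUE)) / prod(dim(arr))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}

#' Laplace-Hamming binarization with a fixed global threshold
#'
#' Filters the volume with the blended Laplacian / Hamming-window frequency
#' response and thresholds at `threshold_fraction` of the filtered in-mask
#' positive maximum. A constant input has no positive range after filtering
#' and yields an empty segmentation with a warning.
#'
#' @param vol An `image_volume` (the relative threshold does not require
#'   density calibration).
#' @param mask `binary_volume` compartment mask on the same grid.
#' @param params An `lh_seg_params`.
#' @return A `binary_volume`; always a subset of `mask`.
#' @export
laplace_hamming_binarize <- function(vol, mask, params = lh_seg_params()) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_volume"))
  if (!identical(dim(vol$data), dim(mask$voxels)))
    stop("mask grid does not match the volume")
  filt <- lh_filter(vol$data, params$hamming_cutoff_fraction,
                    params$epsilon_laplace_weight)
  vals <- filt[mask$voxels]
  scale_ref <- max(abs(vol$data), 1)
  pos_max <- if (length(vals)) max(vals, 0) else 0
  degenerate <- pos_max <= 1e-10 * scale_ref ||
    (max(vals) - min(vals)) <= 1e-10 * scale_ref
  if (degenerate) {
    warning("degenerate (constant or non-positive) filtered input: empty segmentation")
    return(binary_volume(array(FALSE, dim(vol$data)), vol$voxel_um))
  }
  thr <- params$threshold_fraction * pos_max
  binary_volume(filt >= thr & mask$voxels, vol$voxel_um)
}
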