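#' Scanner acquisition profile
#'
#' Describes how a ground-truth structure is degraded into a measured volume:
#' isotropic voxel size, Gaussian point-spread width, additive density noise,
#' and the linear gray-to-density calibration. Two presets mirror the two
#' HR-pQCT generations: `XCTI_like` (82 um voxels) and `XCTII_like` (61 um
#' voxels). The point-spread width defaults to 0.6 voxels so that blur scales
#' with resolution; neither manufacturer publishes a device PSF, so these
#' profiles are qualitative stand-ins, not device models.
#'
#' @param name `"XCTI_like"`, `"XCTII_like"` or `"custom"`.
#' @param voxel_um Voxel size (fixed at 82 / 61 um for the presets).
#' @param psf_sigma_um Gaussian PSF sigma in um (default 0.6 x voxel).
#' @param noise_sd_mgHA SD of additive Gaussian density noise.
#' @param calibration Length-2 numeric `c(slope, intercept)` mapping the
#'   blurred density to stored gray values (identity by default, so volumes
#'   come out calibrated in mgHA/cm3).
#' @return An object of class `scanner_profile`.
#' @export
scanner_profile <- function(name = c("XCTI_like", "XCTII_like", "custom"),
                            voxel_um = NULL, psf_sigma_um = NULL,
                            noise_sd_mgHA = 25,
                            calibration = c(slope = 1, intercept = 0)) {
  name <- match.arg(name)
  if (name == "XCTI_like") {
    if (!is.null(voxel_um) && voxel_um != 82)
      stop("XCTI_like preset has a fixed 82 um voxel; use name = 'custom'")
    voxel_um <- 82
  } else if (name == "XCTII_like") {
    if (!is.null(voxel_um) && voxel_um != 61)
      stop("XCTII_like preset has a fixed 61 um voxel; use name = 'custom'")
    voxel_um <- 61
  } else if (is.null(voxel_um)) stop("custom profile needs voxel_um")
  if (voxel_um <= 0) stop("voxel_um must be positive")
  if (is.null(psf_sigma_um)) psf_sigma_um <- 0.6 * voxel_um
  if (psf_sigma_um < 0) stop("psf_sigma_um must be >= 0")
  if (noise_sd_mgHA < 0) stop("noise_sd_mgHA must be >= 0")
  structure(list(name = name, voxel_um = voxel_um,
                 psf_sigma_um = psf_sigma_um, noise_sd_mgHA = noise_sd_mgHA,
                 calibration = c(slope = unname(calibration[1]),
                                 intercept = unname(calibration[2]))),
            class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("scanner_profile '%s': voxel %.0f um, PSF sigma %.1f um, noise SD %.1f mgHA/cm3\n",
              x$name, x$voxel_um, x$psf_sigma_um, x$noise_sd_mgHA))
  invisible(x)
}

# FFT-domain isotropic Gaussian blur (periodic boundary; the phantom lattices
# are periodic so wrap-around is structure-consistent).
fft_gaussian_blur <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  g <- lapply(d, function(n) {
    f <- fft_freq(n)
    exp(-2 * pi^2 * sigma_vox^2 * f^2)
  })
  A <- fft(arr)
  A <- A * g[[1]]                       # recycles along dim 1
  A <- A * rep(g[[2]], each = d[1])
  A <- A * rep(g[[3]], each = d[1] * d[2])
  Re(fft(A, inverse = TRUE)) / prod(d)
}

# Normalised frequencies (cycles / sample) for an n-point DFT.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / n
}

# Box-average resampling of a 3D array from voxel size vf to vc (vc >= vf),
# separable along axes. Each coarse voxel is the exact area average of the
# fine signal over the interval it covers (fine voxels straddling a coarse
# boundary contribute fractionally), so means and total mass are conserved
# exactly whenever the extent is commensurate with the coarse grid; a partial
# trailing voxel averages just the sliver it covers.
box_resample <- function(arr, voxel_from, voxel_to) {
  if (voxel_to < voxel_from) stop("can only resample to a coarser grid")
  if (voxel_to == voxel_from) return(arr)
  for (axis in 1:3) arr <- bin_axis_mean(arr, axis, voxel_from, voxel_to)
  arr
}

bin_axis_mean <- function(arr, axis, vf, vc) {
  d <- dim(arr)
  n <- d[axis]
  lo <- (seq_len(n) - 1) * vf
  hi <- seq_len(n) * vf
  ncoarse <- ceiling(n * vf / vc - 1e-9)
  j1 <- pmin(floor(lo / vc + 1e-12) + 1L, ncoarse)
  j2 <- pmin(floor(hi / vc - 1e-12) + 1L, ncoarse)
  w2 <- ifelse(j2 > j1, hi - (j2 - 1L) * vc, 0)
  w1 <- (hi - lo) - w2
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  s <- matrix(0, ncoarse, ncol(m))
  wt <- numeric(ncoarse)
  for (i in seq_len(n)) {
    s[j1[i], ] <- s[j1[i], ] + w1[i] * m[i, ]
    wt[j1[i]] <- wt[j1[i]] + w1[i]
    if (w2[i] > 0) {
      s[j2[i], ] <- s[j2[i], ] + w2[i] * m[i, ]
      wt[j2[i]] <- wt[j2[i]] + w2[i]
    }
  }
  s <- s / wt
  dim(s) <- c(ncoarse, d[perm[2]], d[perm[3]])
  aperm(s, order(perm))
}

#' Resample a compartment mask to a coarser grid
#'
#' Majority vote: a coarse voxel belongs to the mask when at least half of
#' the fine volume it covers does.
#'
#' @param mask Logical 3D array.
#' @param voxel_from,voxel_to Fine and coarse voxel sizes (same units).
#' @return Logical array on the coarse grid.
#' @export
resample_mask <- function(mask, voxel_from, voxel_to) {
  box_resample(array(as.numeric(mask), dim(mask)), voxel_from, voxel_to) >= 0.5
}

#' Simulate a scanner acquisition of a ground-truth structure
#'
#' Converts a binary truth volume into a calibrated grayscale volume the way a
#' scanner would see it: solid voxels take the tissue matrix density, the
#' field is convolved with the profile's Gaussian PSF, box-average resampled
#' to the profile's voxel size, mapped through the linear calibration, and
#' corrupted with additive Gaussian noise. Deterministic for a given seed.
#'
#' @param truth A `binary_volume` on a grid at least as fine as the profile's.
#' @param tissue_density_mgHA Matrix density assigned to solid voxels.
#' @param profile A `scanner_profile`.
#' @param seed Integer seed for the noise realization.
#' @return An `image_volume` at `profile$voxel_um`.
#' @export
simulate_scan <- function(truth, tissue_density_mgHA, profile, seed = 1L) {
  stopifnot(inherits(truth, "binary_volume"), inherits(profile, "scanner_profile"))
  if (truth$voxel_um > profile$voxel_um)
    stop("truth grid must be at least as fine as the scanner voxel")
  gray <- array(as.numeric(truth$voxels), dim(truth$voxels)) * tissue_density_mgHA
  sigma_vox <- profile$psf_sigma_um / truth$voxel_um
  gray <- fft_gaussian_blur(gray, sigma_vox)
  gray <- box_resample(gray, truth$voxel_um, profile$voxel_um)
  cal <- profile$calibration
  gray <- cal["slope"] * gray + cal["intercept"]
  if (profile$noise_sd_mgHA > 0) {
    set.seed(as.integer(seed))
    gray <- gray + array(rnorm(length(gray), sd = profile$noise_sd_mgHA), dim(gray))
  }
  image_volume(gray, profile$voxel_um,
               calibrated = isTRUE(all.equal(unname(cal), c(1, 0))))
}
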