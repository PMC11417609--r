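# Small binary fixtures built in code.

make_slab <- function(dims = c(11, 11, 11), axis = 1, from = 4, to = 8) {
  arr <- array(FALSE, dims)
  idx <- slice.index(arr, axis)
  arr[idx >= from & idx <= to] <- TRUE
  arr
}

make_ball <- function(n = 15, radius = 5.5) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array(sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) <= radius,
        c(n, n, n))
}

make_random_blobs <- function(n = 12, seed = 1, p = 0.5, smooth = 1) {
  set.seed(seed)
  f <- array(rnorm(n^3), c(n, n, n))
  for (s in seq_len(smooth)) {
    g <- f
    for (ax in 1:3) {
      lo <- c(2:n, n); hi <- c(1, 1:(n - 1))
      g <- g + switch(ax, f[lo, , ] + f[hi, , ], f[, lo, ] + f[, hi, ],
                      f[, , lo] + f[, , hi])
    }
    f <- g / 7
  }
  f >= quantile(f, 1 - p)
}

thin_plate_spec <- function()
  phantom_spec("plate_lattice", extent_mm = c(2, 1, 1),
               thickness_um = 150, spacing_um = 1000)

fine_pore_shell_spec <- function()
  phantom_spec("cortical_shell", extent_mm = c(3, 3, 0.8), wall_um = 800,
               pore_diameter_um = 75, pore_fraction = 0.02)

thick_plate_spec <- function()
  phantom_spec("plate_lattice", extent_mm = c(6, 0.8, 0.8),
               thickness_um = 3000, spacing_um = 6000)

noise_free_profiles <- function()
  list(xcti = scanner_profile("XCTI_like", noise_sd_mgHA = 0),
       xctii = scanner_profile("XCTII_like", noise_sd_mgHA = 0))

# Segment one phantom arm: simulate, resample the mask, binarize.
segment_arm <- function(ph, profile, method = c("LH", "standard"),
                        compartment = c("trabecular", "cortical"),
                        seed = 5, gp = gaussian_seg_params(),
                        lp = lh_seg_params()) {
  method <- match.arg(method)
  compartment <- match.arg(compartment)
  scan <- simulate_scan(ph$truth, ph$spec$tissue_density_mgHA, profile, seed)
  mask <- binary_volume(resample_mask(ph$masks[[compartment]]$voxels,
                                      ph$truth$voxel_um, profile$voxel_um),
                        profile$voxel_um)
  bone <- if (method == "standard") gaussian_binarize(scan, mask, gp, compartment)
          else laplace_hamming_binarize(scan, mask, lp)
  list(scan = scan, mask = mask, bone = bone)
}
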