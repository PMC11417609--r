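#' Specify a ground-truth bone phantom
#'
#' Defines an analytic structure whose morphometric truth values are known by
#' construction, independently of any raster grid. Four structural families
#' are available:
#' \describe{
#'   \item{plate_lattice}{parallel plates normal to x: `thickness_um`,
#'     `spacing_um` (centre-to-centre pitch).}
#'   \item{rod_lattice}{square lattice of rods along z: `diameter_um`,
#'     `pitch_um`.}
#'   \item{gaussian_field}{thresholded correlated Gaussian random field:
#'     `correlation_um`, `solid_fraction`.}
#'   \item{cortical_shell}{hollow circular cylinder along z with through-going
#'     longitudinal pores: `wall_um`, plus either `pore_fraction` (target pore
#'     volume fraction; pore diameter adjusted to hit it exactly) together
#'     with `pore_diameter_um` as an initial size, or `pore_diameter_um` with
#'     `pore_density_mm3` (pores per mm3 of wall).}
#' }
#'
#' @param kind One of `"plate_lattice"`, `"rod_lattice"`, `"gaussian_field"`,
#'   `"cortical_shell"`.
#' @param extent_mm Length-3 numeric, physical extent in mm.
#' @param tissue_density_mgHA Matrix mineral density of the solid phase.
#' @param seed Integer seed (used only by the `gaussian_field` kind).
#' @param ... Kind-specific structure parameters, see Details.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("plate_lattice", "rod_lattice",
                                  "gaussian_field", "cortical_shell"),
                         extent_mm, tissue_density_mgHA = 1200, seed = 1L, ...) {
  kind <- match.arg(kind)
  extent_mm <- as.numeric(extent_mm)
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 3L)
  if (length(extent_mm) != 3L || any(extent_mm <= 0))
    stop("extent_mm must be a positive 3-vector")
  p <- list(...)
  check_pos <- function(nm) {
    if (is.null(p[[nm]]) || !is.numeric(p[[nm]]) || any(p[[nm]] <= 0))
      stop(sprintf("'%s' must be supplied and positive for kind '%s'", nm, kind))
  }
  if (kind == "plate_lattice") {
    check_pos("thickness_um"); check_pos("spacing_um")
    if (max(p$thickness_um) >= min(p$spacing_um))
      stop("plate thickness must be smaller than plate spacing")
  } else if (kind == "rod_lattice") {
    check_pos("diameter_um"); check_pos("pitch_um")
    if (p$diameter_um >= p$pitch_um)
      stop("rod diameter must be smaller than lattice pitch")
  } else if (kind == "gaussian_field") {
    check_pos("correlation_um")
    if (is.null(p$solid_fraction) || p$solid_fraction <= 0 || p$solid_fraction >= 1)
      stop("solid_fraction must lie in (0, 1)")
  } else { # cortical_shell
    check_pos("wall_um")
    has_pores <- !is.null(p$pore_fraction) || !is.null(p$pore_density_mm3)
    if (has_pores) {
      check_pos("pore_diameter_um")
      if (!is.null(p$pore_fraction) &&
          (p$pore_fraction <= 0 || p$pore_fraction >= 1))
        stop("pore_fraction must lie in (0, 1)")
    }
  }
  structure(c(list(kind = kind, extent_mm = extent_mm,
                   tissue_density_mgHA = tissue_density_mgHA,
                   seed = as.integer(seed)), p),
            class = "phantom_spec")
}

# Smallest structural feature (um) of a phantom, for the raster precondition.
smallest_feature_um <- function(spec) {
  switch(spec$kind,
    plate_lattice = min(min(spec$thickness_um),
                        min(spec$spacing_um) - max(spec$thickness_um)),
    rod_lattice = spec$diameter_um,
    gaussian_field = spec$correlation_um,
    cortical_shell = min(spec$wall_um, spec$pore_diameter_um))
}

# Analytic truth values (grid-independent); NA where the structural family
# does not define the quantity analytically.
phantom_truth <- function(spec) {
  t <- list(bvtv_true = NA_real_, tb_th_true_um = NA_real_,
            tb_sp_true_um = NA_real_, tb_n_true_mm = NA_real_,
            ct_th_true_um = NA_real_, ct_po_true = NA_real_,
            ct_po_dm_true_um = NA_real_)
  if (spec$kind == "plate_lattice") {
    sp <- spec$spacing_um
    th <- rep(spec$thickness_um, length.out = length(sp))
    # interleaved pitches are allowed: mean over the repeating cell
    t$bvtv_true <- sum(th) / sum(sp)
    t$tb_th_true_um <- mean(th)
    t$tb_sp_true_um <- mean(sp - th)
    t$tb_n_true_mm <- 1000 / mean(sp)
  } else if (spec$kind == "rod_lattice") {
    t$bvtv_true <- pi * (spec$diameter_um / 2)^2 / spec$pitch_um^2
    t$tb_th_true_um <- spec$diameter_um
    t$tb_n_true_mm <- 1000 / spec$pitch_um
  } else if (spec$kind == "gaussian_field") {
    t$bvtv_true <- spec$solid_fraction
  } else {
    geo <- shell_geometry(spec)
    t$ct_th_true_um <- spec$wall_um
    t$ct_po_true <- geo$pore_fraction
    t$ct_po_dm_true_um <- 2 * geo$pore_radius_um
  }
  structure(t, class = "phantom_truth")
}

# Resolve the cortical shell geometry: outer/inner radius, pore count, pore
# radius and the realised (exact, analytic) pore volume fraction.
shell_geometry <- function(spec) {
  r_out <- 0.45 * min(spec$extent_mm[1:2]) * 1000
  r_in <- r_out - spec$wall_um
  if (r_in <= 0) stop("shell wall thicker than the available radius")
  area <- pi * (r_out^2 - r_in^2)
  if (is.null(spec$pore_fraction) && is.null(spec$pore_density_mm3)) {
    # solid shell
    return(list(r_out_um = r_out, r_in_um = r_in, n_pores = 0L,
                pore_radius_um = NA_real_, pore_fraction = 0,
                r_mid_um = (r_out + r_in) / 2))
  }
  rp <- spec$pore_diameter_um / 2
  if (!is.null(spec$pore_fraction)) {
    n <- max(1L, round(spec$pore_fraction * area / (pi * rp^2)))
    rp <- sqrt(spec$pore_fraction * area / (n * pi))
  } else {
    wall_vol_mm3 <- area * 1e-6 * spec$extent_mm[3]
    n <- max(1L, round(spec$pore_density_mm3 * wall_vol_mm3))
  }
  frac <- n * pi * rp^2 / area
  r_mid <- (r_out + r_in) / 2
  if (n * 2 * rp >= 2 * pi * r_mid)
    stop("pores overlap: reduce pore count or diameter")
  list(r_out_um = r_out, r_in_um = r_in, n_pores = n,
       pore_radius_um = rp, pore_fraction = frac, r_mid_um = r_mid)
}

#' Rasterize a phantom onto a voxel grid
#'
#' Rasterizes the analytic structure at the requested isotropic voxel size (a
#' voxel is solid when its centre lies inside the structure) and returns the
#' binary truth volume, analytically defined compartment masks, and the
#' grid-independent `phantom_truth` values. Truth values come from the
#' analytic definition, never from the raster.
#'
#' @param spec A `phantom_spec`.
#' @param voxel_um Raster voxel size; must resolve the smallest structural
#'   feature with at least two voxels.
#' @return List with elements `truth` (`binary_volume`), `masks` (named list
#'   of `binary_volume`: `trabecular` and/or `cortical`, plus `total`),
#'   `truth_values` (`phantom_truth`) and `spec`.
#' @export
generate_phantom <- function(spec, voxel_um) {
  stopifnot(inherits(spec, "phantom_spec"))
  feat <- smallest_feature_um(spec)
  if (feat / voxel_um < 2)
    stop(sprintf("unresolvable feature: %.0f um feature is below 2 voxels at %.0f um grid",
                 feat, voxel_um))
  n <- pmax(2L, round(spec$extent_mm * 1000 / voxel_um))
  cx <- (seq_len(n[1]) - 0.5) * voxel_um
  cy <- (seq_len(n[2]) - 0.5) * voxel_um
  cz <- (seq_len(n[3]) - 0.5) * voxel_um

  full <- array(TRUE, n)
  masks <- list()
  if (spec$kind == "plate_lattice") {
    sp <- spec$spacing_um
    th <- rep(spec$thickness_um, length.out = length(sp))
    period <- sum(sp)
    # plates stacked along x; the pattern is shifted so that x = 0 falls at
    # the centre of a gap: plates never touch the volume boundary (where the
    # distance transform treats the structure as continuing), while boundary
    # half-gaps still measure the full gap width
    shift <- (sp[length(sp)] - th[length(th)]) / 2
    xm <- (cx - shift) %% period
    # k-th plate occupies [start_k, start_k + th_k)
    starts <- cumsum(c(0, sp[-length(sp)]))
    solid1d <- rep(FALSE, n[1])
    for (k in seq_along(starts))
      solid1d <- solid1d | (xm >= starts[k] & xm < starts[k] + th[k])
    vox <- array(solid1d, n)
    masks$trabecular <- full
  } else if (spec$kind == "rod_lattice") {
    p <- spec$pitch_um; r <- spec$diameter_um / 2
    dx <- (cx %% p) - p / 2
    dy <- (cy %% p) - p / 2
    disc <- outer(dx^2, dy^2, "+") <= r^2
    vox <- array(disc, n)
    masks$trabecular <- full
  } else if (spec$kind == "gaussian_field") {
    set.seed(spec$seed)
    noise <- array(rnorm(prod(n)), n)
    sigma_vox <- spec$correlation_um / voxel_um
    field <- fft_gaussian_blur(noise, sigma_vox)
    thr <- quantile(field, 1 - spec$solid_fraction)
    vox <- field >= thr
    masks$trabecular <- full
  } else { # cortical_shell
    geo <- shell_geometry(spec)
    x0 <- spec$extent_mm[1] * 1000 / 2
    y0 <- spec$extent_mm[2] * 1000 / 2
    r2 <- outer((cx - x0)^2, (cy - y0)^2, "+")
    annulus <- r2 <= geo$r_out_um^2 & r2 > geo$r_in_um^2
    solid <- annulus
    ang <- (seq_len(geo$n_pores) - 0.5) / geo$n_pores * 2 * pi
    px <- x0 + geo$r_mid_um * cos(ang)
    py <- y0 + geo$r_mid_um * sin(ang)
    for (k in seq_len(geo$n_pores)) {
      d2 <- outer((cx - px[k])^2, (cy - py[k])^2, "+")
      solid <- solid & d2 > geo$pore_radius_um^2
    }
    vox <- array(solid, n)
    masks$cortical <- array(annulus, n)
    # periosteal boundary = outer cylinder surface; total cross-section = disc
    masks$periosteal <- array(r2 <= geo$r_out_um^2, n)
    masks$total <- masks$periosteal
  }
  if (is.null(masks$total)) masks$total <- full
  list(truth = binary_volume(vox, voxel_um),
       masks = lapply(masks, binary_volume, voxel_um = voxel_um),
       truth_values = phantom_truth(spec),
       spec = spec)
}
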