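#' Euclidean distance transform
#'
#' Distance (in um) from every voxel to the centre of the nearest voxel
#' outside the phase. Distances are computed only to background voxels inside
#' the volume; the volume boundary is treated as a continuation of the phase,
#' so slab-like structures spanning the field of view behave as infinite.
#'
#' @param phase A `binary_volume`.
#' @return Numeric array of distances in um (`Inf` where the volume contains
#'   no background).
#' @export
distance_transform <- function(phase) {
  stopifnot(inherits(phase, "binary_volume"))
  d2 <- cpp_edt_sq(!phase$voxels, dim(phase$voxels))
  sqrt(d2) * phase$voxel_um
}

#' Model-independent local thickness
#'
#' For every phase voxel, the diameter of the largest sphere that both fits
#' entirely inside the phase and contains the voxel. Sphere centres are
#' allowed on the half-voxel grid and sphere radii are measured to the phase
#' boundary (half a voxel beyond the nearest background voxel centre), so an
#' n-voxel slab measures n voxels thick for even and odd n alike.
#'
#' @param phase A `binary_volume` (non-empty, with some background).
#' @return Object of class `thickness_map`: list with `um` (array of local
#'   thickness in um, 0 off the phase) and `voxel_um`.
#' @export
local_thickness <- function(phase) {
  stopifnot(inherits(phase, "binary_volume"))
  lt <- cpp_local_thickness(phase$voxels, dim(phase$voxels))
  structure(list(um = lt * phase$voxel_um, voxel_um = phase$voxel_um),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$um[x$um > 0]
  cat(sprintf("thickness_map: %d phase voxels, mean %.1f um, max %.1f um\n",
              length(v), mean(v), max(v)))
  invisible(x)
}

#' Distance ridge (medial axis) of a binary phase
#'
#' Phase voxels whose maximal inscribed sphere is not contained in the sphere
#' of any 26-neighbour.
#'
#' @param phase A `binary_volume`.
#' @return A `binary_volume` marking ridge voxels.
#' @export
distance_ridge <- function(phase) {
  stopifnot(inherits(phase, "binary_volume"))
  binary_volume(cpp_dist_ridge(phase$voxels, dim(phase$voxels)),
                phase$voxel_um)
}

check_same_grid <- function(bone, mask) {
  if (!identical(dim(bone$voxels), dim(mask$voxels)))
    stop("bone and mask are not on the same grid")
}

#' Bone volume fraction
#'
#' @param bone Segmented bone `binary_volume`.
#' @param mask Compartment mask `binary_volume` (non-empty).
#' @return Fraction of mask voxels that are bone.
#' @export
bvtv <- function(bone, mask) {
  check_same_grid(bone, mask)
  nm <- sum(mask$voxels)
  if (nm == 0) stop("empty compartment mask")
  sum(bone$voxels & mask$voxels) / nm
}

# Mean local thickness (mm) of an arbitrary phase restricted to a mask.
mean_thickness_mm <- function(phase_arr, voxel_um, what) {
  if (!any(phase_arr)) stop(sprintf("empty phase: %s undefined", what))
  lt <- cpp_local_thickness(phase_arr, dim(phase_arr))
  mean(lt[phase_arr]) * voxel_um / 1000
}

#' Direct trabecular thickness (mm)
#'
#' Mean local thickness of the bone phase inside the trabecular mask.
#'
#' @param bone,mask `binary_volume`s on one grid.
#' @return Tb.Th in mm.
#' @export
direct_tb_th <- function(bone, mask) {
  check_same_grid(bone, mask)
  mean_thickness_mm(bone$voxels & mask$voxels, bone$voxel_um, "Tb.Th")
}

#' Direct trabecular separation (mm)
#'
#' Mean local thickness of the marrow phase (mask minus bone).
#'
#' @param bone,mask `binary_volume`s on one grid.
#' @return Tb.Sp in mm.
#' @export
direct_tb_sp <- function(bone, mask) {
  check_same_grid(bone, mask)
  mean_thickness_mm(mask$voxels & !bone$voxels, bone$voxel_um, "Tb.Sp")
}

# Inter-axis spacing distribution (mm): medial axes of the trabeculae are the
# distance ridge of the bone phase; the local thickness of everything between
# the axes, plus the one-voxel width of the axis itself, measures the
# centre-to-centre spacing of the trabecular network.
inter_axis_spacing <- function(bone, mask) {
  check_same_grid(bone, mask)
  inb <- bone$voxels & mask$voxels
  if (!any(inb)) stop("no bone within the trabecular mask")
  ridge <- cpp_dist_ridge(inb, dim(inb))
  ncomp <- max(cpp_label26(ridge, dim(ridge)))
  if (ncomp < 2)
    stop("fewer than 2 trabecular elements: spacing between axes undefined")
  between <- mask$voxels & !ridge
  lt <- cpp_local_thickness(between, dim(between))
  (lt[between] + 1) * bone$voxel_um / 1000
}

#' Direct trabecular number (1/mm)
#'
#' Inverse of the mean spacing between the medial axes of the trabeculae.
#'
#' @param bone,mask `binary_volume`s on one grid.
#' @return Tb.N in 1/mm.
#' @export
direct_tb_n <- function(bone, mask) 1 / mean(inter_axis_spacing(bone, mask))

#' Trabecular network inhomogeneity (mm)
#'
#' Standard deviation of the inter-axis spacing distribution (Tb.1/N.SD).
#'
#' @param bone,mask `binary_volume`s on one grid.
#' @return Tb.1/N.SD in mm.
#' @export
tb_1_n_sd <- function(bone, mask) sd(inter_axis_spacing(bone, mask))

#' Indirect (density-derived) trabecular morphometry
#'
#' First-generation-style derivation: bone volume fraction from trabecular
#' density relative to a fully mineralised matrix, thickness and separation
#' from the plate model.
#'
#' @param tb_bmd Trabecular volumetric density (mgHA/cm3).
#' @param tb_n Trabecular number (1/mm), > 0.
#' @param matrix_density_mgHA Matrix mineral density (default 1200).
#' @return Named list with `bvtv`, `tb_th_mm`, `tb_sp_mm`.
#' @export
indirect_morphometry <- function(tb_bmd, tb_n, matrix_density_mgHA = 1200) {
  if (tb_n <= 0) stop("Tb.N must be > 0 for indirect derivation")
  bvtv <- tb_bmd / matrix_density_mgHA
  list(bvtv = bvtv, tb_th_mm = bvtv / tb_n, tb_sp_mm = (1 - bvtv) / tb_n)
}

#' Cortical microstructure metrics
#'
#' Cortical porosity (pore fraction of the compartment), cortical thickness
#' (mean local thickness of the cortical bone) and mean pore diameter (mean
#' local thickness of the pore phase). With no pores, `ct_po` is 0 and
#' `ct_po_dm_mm` is `NA` (flagged missing, not zero).
#'
#' @param bone,mask `binary_volume`s on one grid (mask non-empty).
#' @return Named list with `ct_th_mm`, `ct_po`, `ct_po_dm_mm`.
#' @export
cortical_metrics <- function(bone, mask) {
  check_same_grid(bone, mask)
  nm <- sum(mask$voxels)
  if (nm == 0) stop("empty cortical mask")
  pores <- mask$voxels & !bone$voxels
  ct_po <- sum(pores) / nm
  ct_th <- mean_thickness_mm(bone$voxels & mask$voxels, bone$voxel_um, "Ct.Th")
  ct_po_dm <- if (any(pores))
    mean_thickness_mm(pores, bone$voxel_um, "Ct.Po.Dm") else NA_real_
  list(ct_th_mm = ct_th, ct_po = ct_po, ct_po_dm_mm = ct_po_dm)
}

#' Density and geometry outcomes
#'
#' Volumetric densities are means of the calibrated values over each
#' compartment; areas are mean per-slice cross-sections; the periosteal
#' perimeter is the mean per-slice marching-squares contour length of the
#' periosteal (total) mask.
#'
#' @param vol Calibrated `image_volume`.
#' @param masks Named list of `binary_volume`s; recognised names `total`,
#'   `trabecular`, `cortical` (missing compartments yield `NA` outcomes, but
#'   at least one mask must be present).
#' @return Named list `tt_bmd`, `tb_bmd`, `ct_bmd` (mgHA/cm3), `tb_ar_mm2`,
#'   `ct_ar_mm2`, `ct_pm_mm`.
#' @export
density_geometry <- function(vol, masks) {
  stopifnot(inherits(vol, "image_volume"))
  if (!vol$calibrated) stop("BMD calibration required")
  if (!length(masks)) stop("missing mask")
  for (m in masks) {
    stopifnot(inherits(m, "binary_volume"))
    if (!identical(dim(m$voxels), dim(vol$data)))
      stop("mask grid does not match the volume")
  }
  vx_mm <- vol$voxel_um / 1000
  mean_density <- function(nm)
    if (is.null(masks[[nm]])) NA_real_ else mean(vol$data[masks[[nm]]$voxels])
  slice_area <- function(nm) {
    if (is.null(masks[[nm]])) return(NA_real_)
    m <- masks[[nm]]$voxels
    mean(apply(m, 3, sum)) * vx_mm^2
  }
  peri <- masks$periosteal %||% masks$total %||% masks$cortical
  ct_pm <- if (is.null(peri)) NA_real_ else {
    m <- peri$voxels
    d <- dim(m)
    xs <- (seq_len(d[1]) - 0.5) * vx_mm
    ys <- (seq_len(d[2]) - 0.5) * vx_mm
    per_slice <- vapply(seq_len(d[3]), function(k) {
      sl <- m[, , k]
      # uniform slice: the boundary does not cross the field of view
      if (all(sl) || !any(sl)) return(0)
      cl <- contourLines(xs, ys, sl * 1, levels = 0.5)
      if (!length(cl)) return(0)
      sum(vapply(cl, function(cc) {
        x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
        sum(sqrt(diff(x)^2 + diff(y)^2))
      }, numeric(1)))
    }, numeric(1))
    mean(per_slice)
  }
  list(tt_bmd = mean_density("total"), tb_bmd = mean_density("trabecular"),
       ct_bmd = mean_density("cortical"), tb_ar_mm2 = slice_area("trabecular"),
       ct_ar_mm2 = slice_area("cortical"), ct_pm_mm = ct_pm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
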