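test_that("local thickness equals the brute-force inscribed-sphere oracle", {
  fixtures <- list(slab = make_slab(),
                   ball = make_ball(),
                   blobs1 = make_random_blobs(12, seed = 1),
                   blobs2 = make_random_blobs(12, seed = 2, p = 0.3),
                   plates = {
                     a <- array(FALSE, c(16, 16, 16))
                     a[4:6, , ] <- TRUE; a[11:14, , ] <- TRUE; a
                   })
  for (nm in names(fixtures)) {
    ph <- fixtures[[nm]]
    lt <- local_thickness(binary_volume(ph, 1))$um
    expect_equal(lt, oracle_local_thickness(ph), tolerance = 1e-9,
                 info = nm)
  }
})

test_that("distance transform equals brute-force enumeration", {
  ph <- make_random_blobs(10, seed = 3)
  dt <- distance_transform(binary_volume(ph, 1))
  oracle <- sqrt(oracle_edt(ph))
  expect_equal(dt, oracle, tolerance = 1e-9)
})

test_that("canonical shapes measure their known thickness", {
  slab <- local_thickness(binary_volume(make_slab(), 1))
  vals <- slab$um[make_slab()]
  expect_true(all(abs(vals - 5) <= 0.5))       # 5-voxel slab, everywhere
  ball <- local_thickness(binary_volume(make_ball(), 1))
  expect_true(abs(max(ball$um) - 11) <= 1)     # 11-voxel ball
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(max(local_thickness(binary_volume(single, 1))$um), 1)
})

test_that("bone volume fraction is a straight voxel ratio", {
  d <- c(10, 10, 10)
  mask <- binary_volume(array(TRUE, d), 61)
  half <- array(FALSE, d); half[1:5, , ] <- TRUE
  expect_equal(bvtv(binary_volume(half, 61), mask), 0.5)
  expect_equal(bvtv(binary_volume(array(FALSE, d), 61), mask), 0)
  expect_error(bvtv(binary_volume(half, 61),
                    binary_volume(array(FALSE, d), 61)), "empty")
})

test_that("direct thickness and separation recover plate-lattice truth", {
  g <- generate_phantom(phantom_spec("plate_lattice", extent_mm = c(2, 1, 1),
                                     thickness_um = 200, spacing_um = 1000), 20)
  expect_equal(direct_tb_th(g$truth, g$masks$trabecular), 0.200,
               tolerance = 0.02 / 0.200)
  expect_equal(direct_tb_sp(g$truth, g$masks$trabecular), 0.800,
               tolerance = 0.04 / 0.800)
})

test_that("separation is undefined for an all-solid compartment", {
  d <- c(8, 8, 8)
  solid <- binary_volume(array(TRUE, d), 61)
  expect_error(direct_tb_sp(solid, solid), "empty phase")
})

test_that("trabecular number and inhomogeneity follow the lattice pitch", {
  g <- generate_phantom(phantom_spec("plate_lattice", extent_mm = c(2, 1, 1),
                                     thickness_um = 200, spacing_um = 1000), 20)
  expect_equal(direct_tb_n(g$truth, g$masks$trabecular), 1.0,
               tolerance = 0.05)
  expect_lt(tb_1_n_sd(g$truth, g$masks$trabecular), 0.02)
  gi <- generate_phantom(phantom_spec("plate_lattice", extent_mm = c(2, 1, 1),
                                      thickness_um = 200,
                                      spacing_um = c(800, 1200)), 20)
  expect_equal(tb_1_n_sd(gi$truth, gi$masks$trabecular),
               sqrt(0.4 * 0.6) * 0.4, tolerance = 0.2)
})

test_that("a single trabecular element cannot define a spacing", {
  d <- c(20, 10, 10)
  one <- array(FALSE, d); one[9:11, , ] <- TRUE
  m <- binary_volume(array(TRUE, d), 50)
  expect_error(direct_tb_n(binary_volume(one, 50), m), "fewer than 2")
})

test_that("indirect morphometry is the plate-model arithmetic", {
  r <- indirect_morphometry(240, 2.0, 1200)
  expect_equal(r$bvtv, 0.2)
  expect_equal(r$tb_th_mm, 0.1)
  expect_equal(r$tb_sp_mm, 0.4)
  expect_equal(indirect_morphometry(0, 2)$tb_th_mm, 0)
  expect_equal(indirect_morphometry(0, 2)$tb_sp_mm, 0.5)
  expect_equal(indirect_morphometry(1200, 2)$tb_sp_mm, 0)
  expect_error(indirect_morphometry(240, 0), "Tb.N")
})

test_that("cortical metrics recover shell truth", {
  solid <- generate_phantom(phantom_spec("cortical_shell",
                                         extent_mm = c(3.6, 3.6, 0.4),
                                         wall_um = 1200), 20)
  cm <- cortical_metrics(solid$truth, solid$masks$cortical)
  expect_equal(cm$ct_th_mm, 1.2, tolerance = 0.06 / 1.2)
  expect_equal(cm$ct_po, 0)
  expect_true(is.na(cm$ct_po_dm_mm))

  porous <- generate_phantom(phantom_spec("cortical_shell",
                                          extent_mm = c(2, 2, 0.3),
                                          wall_um = 400,
                                          pore_diameter_um = 150,
                                          pore_fraction = 0.10), 10)
  cmp <- cortical_metrics(porous$truth, porous$masks$cortical)
  expect_equal(cmp$ct_po, 0.10, tolerance = 0.01 / 0.10)
  expect_equal(cmp$ct_po_dm_mm, 0.150, tolerance = 0.02 / 0.150)
})

test_that("density and geometry outcomes match analytic values", {
  d <- c(60, 60, 5)
  vox <- 100  # 0.1 mm
  arr <- array(300, d)
  cx <- ((1:60) - 0.5) * 0.1 - 3
  disc <- outer(cx^2, cx^2, "+") <= 2.5^2          # circle r = 2.5 mm
  sq <- array(FALSE, d); sq[11:50, 11:50, ] <- TRUE  # square side 4 mm
  masks <- list(trabecular = binary_volume(array(disc, d), vox),
                periosteal = binary_volume(sq, vox),
                total = binary_volume(array(TRUE, d), vox))
  dg <- density_geometry(image_volume(arr, vox), masks)
  expect_equal(dg$tb_bmd, 300)
  expect_equal(dg$tb_ar_mm2, pi * 2.5^2, tolerance = 0.01)
  expect_equal(dg$ct_pm_mm, 16, tolerance = 0.02)
  expect_error(density_geometry(image_volume(arr, vox), list()), "mask")
})

test_that("outcomes are invariant to translation and axis permutation", {
  g <- generate_phantom(phantom_spec("plate_lattice", extent_mm = c(1, 0.6, 0.6),
                                     thickness_um = 200, spacing_um = 500), 20)
  base <- g$truth$voxels
  m <- g$masks$trabecular
  ref <- c(bvtv(g$truth, m), direct_tb_th(g$truth, m),
           direct_tb_sp(g$truth, m))
  d <- dim(base)
  # a circular shift by one lattice period (500 um = 25 voxels) relocates
  # every plate onto another plate's position: outcomes must not move
  per <- base[c(26:d[1], 1:25), , ]
  bvp <- binary_volume(per, 20)
  expect_equal(c(bvtv(bvp, m), direct_tb_th(bvp, m), direct_tb_sp(bvp, m)),
               ref, tolerance = 1e-12)
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    pv <- binary_volume(aperm(base, perm), 20)
    pm <- binary_volume(aperm(m$voxels, perm), 20)
    expect_equal(c(bvtv(pv, pm), direct_tb_th(pv, pm), direct_tb_sp(pv, pm)),
                 ref, tolerance = 1e-12)
  }
})

test_that("direct and indirect bone volume fraction agree on a resolved phantom", {
  g <- generate_phantom(thick_plate_spec(), 20)
  p <- scanner_profile("XCTII_like", noise_sd_mgHA = 0)
  arm <- segment_arm(g, p, "standard")
  direct <- bvtv(arm$bone, arm$mask)
  indirect <- indirect_morphometry(mean(arm$scan$data[arm$mask$voxels]),
                                   1, 1200)$bvtv
  expect_equal(direct, indirect, tolerance = 0.02)
})
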