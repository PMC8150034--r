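make_tube_mask <- function(nx = 40, nz = 40, router = 15, rinner = 9,
                           axis = 3) {
  g <- seq_len(nx) - (nx + 1) / 2
  r2 <- outer(g^2, g^2, `+`)
  sl <- r2 <= router^2 & r2 > rinner^2
  m <- array(FALSE, c(nx, nx, nz))
  for (k in seq_len(nz)) m[, , k] <- sl
  if (axis == 1) m <- aperm(m, c(3, 1, 2))
  m
}

test_that("long-axis alignment maps the principal axis onto the slice axis", {
  sp <- 20
  m_z <- make_tube_mask()
  al <- align_long_axis(m_z, sp)
  expect_equal(al$rotation, diag(3))
  expect_lt(al$angle_deg, 1)
  # cylinder along x gets rotated; post-rotation principal angle < 2 deg
  m_x <- make_tube_mask(axis = 1)
  al2 <- align_long_axis(m_x, sp)
  co <- arrayInd(which(al2$mask), dim(al2$mask)) - 1
  eg <- eigen(stats::cov(co), symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  expect_lt(acos(min(1, abs(v1[3]))) * 180 / pi, 2)
  # sphere: isotropic inertia -> identity + degeneracy flag
  g <- seq_len(21) - 11
  ball <- array(outer(outer(g^2, g^2, `+`), g^2, `+`) <= 8^2, c(21, 21, 21))
  al3 <- align_long_axis(ball, sp)
  expect_true(al3$degenerate)
  expect_equal(al3$rotation, diag(3))
})

test_that("compartment labels: tube, tube+rods, solid cylinder", {
  sp <- 25
  # hollow tube phantom, noise-free: all bone cortical
  tube <- make_long_bone(small_bone_spec(1, model = "none",
                                         blur_sigma_vox = 0, noise_sd_frac = 0))
  lab <- segment_volume(tube$volume)$label
  expect_equal(sum(lab$labels == 2L), 0L)
  expect_gt(sum(lab$labels == 3L), 0L)
  # tube + rod lattice, noise-free: trabecular Dice >= 0.95 vs ground truth
  ph <- make_long_bone(small_bone_spec(2, blur_sigma_vox = 0,
                                       noise_sd_frac = 0))
  lab2 <- segment_volume(ph$volume)$label
  expect_gte(dice_coef(lab2$labels == 2L, ph$truth$labels$labels == 2L), 0.95)
  # labels partition the grid and bone is conserved exactly
  mask <- threshold_bone(ph$volume)
  seg <- segment_compartments(mask, sp)
  expect_equal(sum(tabulate(seg$labels + 1L, 4L)), length(seg$labels))
  expect_equal(seg$labels %in% 1:2, as.vector(mask))
  # solid cylinder: all bone cortical, no internal space
  g <- seq_len(40) - 20.5
  solid <- array(FALSE, c(40, 40, 30))
  for (k in 5:26) solid[, , k] <- outer(g^2, g^2, `+`) <= 14^2
  labs <- segment_compartments(solid, sp)
  expect_equal(sum(labs$labels == 2L), 0L)
  expect_equal(sum(labs$labels == 3L), 0L)
})

test_that("whole-bone mask equals the filled periosteal volume", {
  ph <- make_long_bone(small_bone_spec(3, blur_sigma_vox = 0,
                                       noise_sd_frac = 0))
  lab <- segment_volume(ph$volume)$label
  wb <- whole_bone_mask(lab)
  # superset of bone voxels
  expect_true(all(wb[lab$labels %in% 1:2]))
  # volume matches the analytic cylinder within 2% (caps included in truth)
  expect_equal(sum(wb), sum(ph$truth$labels$labels > 0L), tolerance = 0.02)
  # empty label volume gives an empty mask
  empty <- label_volume(array(0L, c(4, 4, 4)), 25)
  expect_false(any(whole_bone_mask(empty)))
})

test_that("trabecular denoising removes specks, conserves voxel counts", {
  lab <- array(0L, c(20, 20, 20))
  lab[5:15, 5:15, 5:15] <- 3L
  lab[6:14, 10, 6:14] <- 2L       # 81-voxel plate: stays
  lab[17, 17, 17] <- 2L           # isolated speck: goes
  lab[2:3, 2, 2] <- 2L            # 2-voxel speck: goes
  lv <- label_volume(lab, 25)
  out <- denoise_trabecular(lv, min_component = 27L)
  expect_equal(sum(out$labels == 2L), 81L)
  expect_equal(out$labels[17, 17, 17], 3L)
  expect_equal(length(out$labels), length(lv$labels))
  expect_equal(tabulate(out$labels + 1L, 4L)[1:2], tabulate(lab + 1L, 4L)[1:2])
  # a large connected network is untouched
  big <- array(0L, c(30, 30, 30)); big[5:25, 5:25, 5:25] <- 3L
  big[10:20, 10:20, 10:20] <- 2L
  out2 <- denoise_trabecular(label_volume(big, 25), 27L)
  expect_equal(sum(out2$labels == 2L), 11^3)
})

test_that("midshaft search finds the waist, then the thickest cortex", {
  # sinusoidal outer radius: waist (narrowest circumference) at mid-length
  ph <- make_long_bone(phantom_spec(
    length_um = 4000, outer_radius_um = c(700, 1000),
    cortical_thickness_um = 250, trabecular_model = "none",
    blur_sigma_vox = 0, noise_sd_frac = 0, spacing_um = 25))
  lab <- segment_volume(ph$volume, segmentation_config(axis_align = FALSE))$label
  ms <- find_midshaft(lab)
  d3 <- dim(lab$labels)[3]
  expect_true(abs(ms$slice_index - d3 / 2) <= 0.1 * d3)
  expect_true(ms$slice_index %in% ms$search_window)
  # flip symmetry: the mirrored volume yields the mirrored search window,
  # and the chosen slice is one of the mirrored candidates (exact ties at
  # symmetric positions may resolve to either member of the pair)
  flip <- label_volume(lab$labels[, , d3:1], lab$spacing)
  ms2 <- find_midshaft(flip)
  expect_equal(sort(d3 + 1 - ms2$search_window), sort(ms$search_window))
  expect_true((d3 + 1 - ms2$slice_index) %in% ms$search_window)
  expect_equal(ms$cortical_area_profile[ms$slice_index],
               ms2$cortical_area_profile[ms2$slice_index], tolerance = 1e-9)
  # constant tube, constant cortex: tie-break picks a central slice
  tube <- make_long_bone(small_bone_spec(5, model = "none",
                                         blur_sigma_vox = 0, noise_sd_frac = 0))
  labt <- segment_volume(tube$volume, segmentation_config(axis_align = FALSE))$label
  mst <- find_midshaft(labt)
  expect_true(abs(mst$slice_index - mean(mst$search_window)) <=
                diff(range(mst$search_window)) / 2)
  expect_error(find_midshaft(label_volume(array(0L, c(5, 5, 12)), 25)),
               "no bone")
})

test_that("noisy-phantom trabecular Dice stays high across seeds (SNR 5)", {
  dices <- vapply(1:5, function(s) {
    ph <- make_long_bone(small_bone_spec(100 + s))
    lab <- segment_phantom(ph)$label
    dice_coef(lab$labels == 2L, ph$truth$labels$labels == 2L)
  }, numeric(1))
  expect_true(all(dices >= 0.9))
})
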