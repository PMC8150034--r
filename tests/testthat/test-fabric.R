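test_that("lattice spacing follows the trabecular-width rule with 50% overlap", {
  lab <- label_volume(array(2L, c(10, 10, 10)), 100)  # 1 mm cube of label 2
  lat1 <- build_lattice(lab, tb_th_um = 100)
  expect_equal(lat1$spacing, 500); expect_equal(lat1$radius, 500)
  lat2 <- build_lattice(lab, tb_th_um = 200)
  expect_equal(lat2$spacing, 600); expect_equal(lat2$radius, 600)
  # overlap of adjacent spherical neighbourhoods: (2r - s) / 2r = 1/2
  expect_equal((2 * lat1$radius - lat1$spacing) / (2 * lat1$radius), 0.5)
  # cubic ROI of edge 2000 µm at s = 500: 4 interior centres per axis
  lab2 <- label_volume(array(2L, c(21, 21, 21)), 100)
  lat3 <- build_lattice(lab2, tb_th_um = 120)
  expect_equal(nrow(lat3$centres), 64L)
  expect_error(build_lattice(label_volume(array(3L, c(4, 4, 4)), 100), 100),
               "empty")
})

test_that("fabric tensor closed forms: equator, plates, uniform sphere", {
  set.seed(6)
  # normals on the equator (cylinder wall along z)
  th <- runif(5000, 0, 2 * pi)
  eq <- cbind(cos(th), sin(th), 0)
  ft <- fabric_tensor(eq)
  expect_equal(ft$eigenvalues, c(0.5, 0.5, 0), tolerance = 0.02)
  expect_equal(ft$da, 1)
  expect_gt(abs(ft$axis[3]), 0.999)
  expect_false(ft$degenerate)
  # all normals +-z (plate stack): eigenvalues (1,0,0), axis ambiguous
  pl <- matrix(c(0, 0, 1), 300, 3, byrow = TRUE) * sample(c(-1, 1), 300, TRUE)
  fp <- fabric_tensor(pl)
  expect_equal(fp$eigenvalues, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fp$da, 1)
  expect_true(fp$degenerate)
  # uniform normals: C -> I/3, da -> 0
  fu <- fabric_tensor(osteofabric:::runif_sphere(10000))
  expect_lt(fu$da, 0.05)
  # below min_count: undefined sample with the zero sentinel
  f0 <- fabric_tensor(eq[1:10, ], min_count = 50)
  expect_false(f0$defined)
  expect_equal(f0$da, 0)
  # eigenvalues always sum to one for defined samples
  for (s in 1:5) {
    set.seed(s)
    ff <- fabric_tensor(osteofabric:::rvmf(200, c(0, 0, 1), 5))
    expect_equal(sum(ff$eigenvalues), 1, tolerance = 1e-9)
    expect_true(ff$da >= 0 && ff$da <= 1)
  }
})

test_that("surface normals follow slab faces and sphere radii", {
  sp <- 25
  slab <- array(FALSE, c(16, 16, 16)); slab[, , 6:10] <- TRUE
  sn <- surface_normals(slab, sp)
  expect_gt(nrow(sn$normals), 0)
  ang <- acos(pmin(1, abs(sn$normals[, 3]))) * 180 / pi
  expect_lt(max(ang), 5)
  # digital ball: normals within 15 degrees of radial
  g <- seq_len(25) - 13
  ball <- array(outer(outer(g^2, g^2, `+`), g^2, `+`) <= 9^2, c(25, 25, 25))
  snb <- surface_normals(ball, sp)
  co <- sweep(snb$points / sp, 2, c(12, 12, 12))  # voxel offsets from centre
  rad <- co / sqrt(rowSums(co^2))
  cosang <- abs(rowSums(rad * snb$normals))
  expect_gt(mean(acos(pmin(1, cosang)) * 180 / pi < 15), 0.95)
  # structure with no surface: empty set
  sn_empty <- surface_normals(array(FALSE, c(6, 6, 6)), sp)
  expect_equal(nrow(sn_empty$normals), 0L)
})

test_that("whole-bone anisotropy maps separate aligned from isotropic fabrics", {
  ph_a <- make_long_bone(small_bone_spec(41, scatter_deg = 7))
  lab_a <- segment_phantom(ph_a)$label
  tb_a <- local_thickness(lab_a$labels == 2L, 25)$mean_um
  fld_a <- map_anisotropy(lab_a, build_lattice(lab_a, tb_a))
  sa <- fld_a$samples[fld_a$samples$defined, ]
  # >= 90% of defined samples align with the rod axis within 15 degrees
  expect_gt(mean(acos(pmin(1, abs(sa$az))) * 180 / pi < 15), 0.9)
  ph_i <- make_long_bone(small_bone_spec(41, model = "isotropic_rods"))
  lab_i <- segment_phantom(ph_i)$label
  tb_i <- local_thickness(lab_i$labels == 2L, 25)$mean_um
  fld_i <- map_anisotropy(lab_i, build_lattice(lab_i, tb_i))
  si <- fld_i$samples[fld_i$samples$defined, ]
  expect_gt(median(sa$da), median(si$da))
  # a ball entirely in open space carries the zero sentinel
  lab_c <- lab_a
  lattice_far <- list(spacing = 500, radius = 300,
                      centres = matrix(c(60, 60, 60), 1, 3,
                                       dimnames = list(NULL, c("x", "y", "z"))))
  class(lattice_far) <- "sampling_lattice"
  fld_c <- map_anisotropy(lab_c, lattice_far)
  expect_equal(fld_c$samples$da, 0)
  expect_false(fld_c$samples$defined)
})

test_that("DA histogram excludes the zero sentinel and takes the lower tie", {
  f <- toy_field(da = c(0, 0.31, 0.33, 0.72), z = 1:4)
  h <- da_histogram(f, 0.05)
  expect_equal(sum(h$counts), 3L)
  expect_equal(h$n_defined, 3L)
  expect_equal(h$mode, 0.325)   # bin [0.30, 0.35) holds two samples
  # tie between two bins resolves to the lower bin
  f2 <- toy_field(da = c(0.12, 0.62), z = 1:2)
  expect_equal(da_histogram(f2, 0.05)$mode, 0.125)
  # all-zero field: empty histogram, undefined mode
  h0 <- da_histogram(toy_field(da = c(0, 0), z = 1:2))
  expect_true(is.na(h0$mode))
  expect_equal(sum(h0$counts), 0L)
})

test_that("high-anisotropy filter is boundary-inclusive", {
  f <- toy_field(da = c(0.5, 0.65, 0.9), z = 1:3)
  expect_equal(nrow(filter_high(f, 0.65)$samples), 2L)
  expect_equal(nrow(filter_high(f, 0)$samples), 3L)
  expect_equal(nrow(filter_high(f, 1.01)$samples), 0L)
})

test_that("coherence: closed forms and aligned vs isotropic regions", {
  mk <- function(axes, z) {
    s <- data.frame(x = 0, y = 0, z = z, da = 0.8,
                    ax = axes[, 1], ay = axes[, 2], az = axes[, 3],
                    n_normals = 100L, degenerate = FALSE, defined = TRUE)
    structure(list(samples = s, lattice = list(spacing = 500, radius = 500)),
              class = "anisotropy_field")
  }
  n <- 300
  aligned <- mk(matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE),
                z = runif(n, 0, 3000))
  expect_equal(coherence(aligned)$coherence, rep(1, 3), tolerance = 1e-9)
  set.seed(8)
  iso <- mk(osteofabric:::runif_sphere(10000), z = runif(10000, 0, 3000))
  expect_true(all(coherence(iso)$coherence < 0.05))
  # fewer than 5 samples in a region: undefined
  tiny <- mk(matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE), z = 1:4)
  expect_true(all(is.na(coherence(tiny, n_regions = 3)$coherence[2:3])))
})

test_that("MIL fabric agrees with closed geometry and rod phantoms", {
  # solid ball: near-equal intercepts, low anisotropy
  g <- seq_len(31) - 16
  ball <- array(outer(outer(g^2, g^2, `+`), g^2, `+`) <= 12^2, c(31, 31, 31))
  mb <- mil_fabric(ball, 25, n_directions = 64)
  expect_lt(mb$da, 0.1)
  # aligned rods: axis within 15 degrees of truth
  rc <- make_rod_cube(edge_um = 1200, model = "aligned_rods", scatter_deg = 8,
                      rod_radius_um = 60, target_fill = 0.3, spacing_um = 25,
                      seed = 5)
  mr <- mil_fabric(rc$mask, 25, n_directions = 64)
  expect_lt(acos(min(1, abs(mr$axis[3]))) * 180 / pi, 15)
  expect_error(mil_fabric(array(FALSE, c(8, 8, 8)), 25), "usable")
})

test_that("fabric is rotation-equivariant and monotone in rod alignment", {
  rc <- make_rod_cube(edge_um = 1200, model = "aligned_rods", scatter_deg = 8,
                      rod_radius_um = 60, target_fill = 0.3, spacing_um = 25,
                      seed = 13)
  f0 <- fabric_tensor(surface_normals(rc$mask, 25)$normals)
  # rotate the cube 90 degrees about y: x -> -z (axis z -> x)
  rot <- aperm(rc$mask, c(3, 2, 1))[dim(rc$mask)[3]:1, , ]
  f90 <- fabric_tensor(surface_normals(rot, 25)$normals)
  expect_lt(abs(f90$da - f0$da), 0.05)
  expect_lt(acos(min(1, abs(f90$axis[1]))) * 180 / pi, 10)
  # median da strictly increases as angular scatter tightens
  med <- vapply(c(60, 40, 25, 12, 5), function(sc) {
    m <- make_rod_cube(edge_um = 1200, scatter_deg = sc, rod_radius_um = 60,
                       target_fill = 0.3, spacing_um = 25, seed = 17)$mask
    fabric_tensor(surface_normals(m, 25)$normals)$da
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})
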