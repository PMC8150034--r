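test_that("midshaft binarization: idempotence, largest component, fractions", {
  cs <- make_cross_section(fill = 0, spacing_um = 20)
  expect_equal(binarize_midshaft(cs$section), cs$section)
  withdust <- cs$section
  withdust[2:3, 2:3] <- TRUE
  expect_equal(binarize_midshaft(withdust), cs$section)
  # bimodal grayscale slice recovers the constructed bright fraction
  set.seed(2)
  n <- 120; g <- seq_len(n) - (n + 1) / 2
  bright <- outer(g^2, g^2, `+`) <= 40^2       # one connected bright disc
  gray <- matrix(rnorm(n^2, 60, 6), n, n)
  gray[bright] <- rnorm(sum(bright), 210, 6)
  bw <- binarize_midshaft(gray)
  expect_equal(mean(bw), mean(bright), tolerance = 0.02)
})

test_that("section centres: symmetry, offset cavities, solid fallback", {
  cs <- make_cross_section(outer_radius_um = 1200, cortical_thickness_um = 300,
                           spacing_um = 20)
  cen <- compute_centres(cs$section, 20)
  mid <- (dim(cs$section) + 1) / 2
  expect_lt(max(abs(cen$section_centre - mid)), 1)
  expect_lt(max(abs(cen$medullary_centre - mid)), 1)
  expect_lt(max(abs(cen$ontogenetic_centre - mid)), 1.6)
  # cavity shifted +10 px in x: medullary centre follows, section centre stays
  n <- 120; g <- seq_len(n) - (n + 1) / 2
  sec <- outer(g^2, g^2, `+`) <= 50^2
  cav <- outer((g - 10)^2, g^2, `+`) <= 25^2
  off <- sec & !cav
  cen2 <- compute_centres(off, 20)
  expect_equal(cen2$medullary_centre[1] - cen2$section_centre[1], 10,
               tolerance = 0.15)
  expect_lt(abs(cen2$section_centre[1] - (n + 1) / 2), 1.1)
  # solid disc: medullary centre falls back to the section centre
  cen3 <- compute_centres(sec, 20)
  expect_equal(cen3$medullary_centre, cen3$section_centre)
})

test_that("radial profile geometry: disc, annulus, missing wedge", {
  n <- 140; g <- seq_len(n) - (n + 1) / 2
  cen <- c((n + 1) / 2, (n + 1) / 2)
  disc <- outer(g^2, g^2, `+`) <= 60^2
  pr <- radial_profile(disc, cen)
  expect_true(all(pr$profile[!is.na(pr$profile)] > 0.999))
  # annulus with inner radius = 0.5 outer: compactness 0 inside, 1 outside
  ann <- disc & !(outer(g^2, g^2, `+`) <= 30^2)
  pra <- radial_profile(ann, cen)
  inner <- pra$profile[, pra$radial_mid < 0.45]
  outer_ <- pra$profile[, pra$radial_mid > 0.55 & pra$radial_mid < 0.98]
  expect_lt(mean(inner, na.rm = TRUE), 0.05)
  expect_gt(mean(outer_, na.rm = TRUE), 0.95)
  # 90-degree missing wedge: a quarter of the sectors is undefined
  ang <- atan2(rep(g, each = n), rep(g, n)) %% (2 * pi)
  wedge <- ann & !(matrix(ang, n, n, byrow = TRUE) < pi / 2)
  prw <- radial_profile(wedge, cen, n_sectors = 60)
  undef <- sum(apply(prw$profile, 1, function(x) all(is.na(x))))
  expect_equal(undef, 15, tolerance = 1)
  # pixel conservation: occupied counts over all cells = bone pixel count
  expect_equal(sum(pra$profile * pra$counts, na.rm = TRUE), sum(ann))
})

test_that("sigmoid fits recover parameters and flag degenerate profiles", {
  d <- seq(0.01, 0.99, length.out = 60)
  truth <- c(min = 0.1, max = 0.95, p = 0.5, s = 0.05)
  sig <- function(d, p) p[1] + (p[2] - p[1]) / (1 + exp((p[3] - d) / p[4]))
  # noise-free recovery < 1% for S >= 0.02
  for (s_par in c(0.02, 0.05, 0.15)) {
    pp <- c(0.1, 0.95, 0.5, s_par)
    f <- osteofabric:::fit_sigmoid_1d(d, sig(d, pp))
    expect_lt(max(abs(unlist(f[c("min", "max", "p", "s")]) - pp) / pp), 0.01)
  }
  # noisy recovery within 10%
  set.seed(31)
  noisy <- sig(d, truth) + rnorm(60, 0, 0.01)
  f2 <- osteofabric:::fit_sigmoid_1d(d, pmin(pmax(noisy, 0), 1))
  expect_lt(max(abs(unlist(f2[c("min", "max", "p", "s")]) - truth) / truth), 0.10)
  # solid disc: flat profile, degenerate flag
  n <- 100; g <- seq_len(n) - (n + 1) / 2
  disc <- outer(g^2, g^2, `+`) <= 45^2
  prd <- radial_profile(disc, c((n + 1) / 2, (n + 1) / 2))
  fd <- fit_sigmoid(prd, "global")
  expect_true(fd$degenerate)
  expect_gt(fd$min, 0.95)
  # trabeculae-filled cavity: fitted Rmin clearly above zero
  cs <- make_cross_section(fill = 0.5, seed = 12)
  an <- analyse_midshaft(cs$section, cs$spacing_um)
  expect_gt(an$angular$mean["min"], 0.2)
  expect_gt(an$global$min, 0.2)
  # open cavity: Rmin near zero
  cs0 <- make_cross_section(fill = 0)
  an0 <- analyse_midshaft(cs0$section, cs0$spacing_um)
  expect_lt(an0$angular$mean["min"], 0.05)
})

test_that("observed compactness: closed forms and rotation invariance", {
  n <- 140; g <- seq_len(n) - (n + 1) / 2
  r2 <- outer(g^2, g^2, `+`)
  disc <- r2 <= 60^2
  expect_equal(observed_compactness(disc), 1.0)
  ann <- disc & !(r2 <= 30^2)
  expect_equal(observed_compactness(ann), 0.75, tolerance = 0.01)
  # checkerboard-filled cavity: 0.75 + 0.5 * 0.25 = 0.875
  chk <- ann | (r2 <= 30^2 & (row(ann) + col(ann)) %% 2 == 0)
  expect_equal(observed_compactness(chk), 0.875, tolerance = 0.01)
  for (rot in 1:3) {
    expect_equal(observed_compactness(t(ann)[, n:1]), observed_compactness(ann))
  }
})

test_that("lifestyle discriminant: refit separates fills, boundary is aquatic", {
  # labelled sections: open cavities (terrestrial) vs filled (aquatic)
  train <- do.call(rbind, lapply(1:6, function(i) {
    fill <- if (i <= 3) 0 else 0.55
    cs <- make_cross_section(fill = fill, seed = i,
                             outer_radius_um = 1200,
                             cortical_thickness_um = 350, spacing_um = 25)
    an <- analyse_midshaft(cs$section, 25)
    data.frame(Rmin = unname(an$angular$mean["min"]),
               lifestyle = if (fill == 0) "terrestrial" else "aquatic")
  }))
  coefs <- fit_lifestyle_coefficients(train)
  expect_equal(classify_lifestyle(c(Rmin = 0), coefs)$call, "terrestrial")
  expect_equal(classify_lifestyle(c(Rmin = 0.9), coefs)$call, "aquatic")
  # boundary score = 0 resolves to aquatic
  ident <- list(intercept = -0.4, coef = c(Rmin = 1), id = "identity")
  expect_equal(classify_lifestyle(c(Rmin = 0.4), ident)$call, "aquatic")
  expect_error(classify_lifestyle(c(Rmax = 1), ident), "missing")
})
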