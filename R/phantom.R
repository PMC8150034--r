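#' Parametric synthetic long-bone specification
#'
#' Describes a tubular cortex with an optional trabecular network in the
#' medullary cavity, plus imaging degradation. Serves as the validation
#' fixture for every stage: the generator returns exact compartment
#' labels and a per-voxel strut orientation field.
#'
#' Trabecular models: `aligned_rods` draws rod axes from a von
#' Mises--Fisher distribution with angular scatter `scatter_deg` about
#' `axis` (terrestrial-like fabric); `isotropic_rods` draws axes
#' uniformly on the sphere (aquatic/semi-aquatic-like fabric); `plates`
#' stacks parallel plates (exercises the degenerate-fabric flag);
#' `none` leaves the cavity open.
#'
#' @param length_um bone length, µm.
#' @param outer_radius_um shaft outer radius, µm; either a single value
#'   or `c(min, max)` for a sinusoidal radius profile with the waist at
#'   mid-length.
#' @param cortical_thickness_um cortical wall thickness, µm.
#' @param trabecular_model `"none"`, `"aligned_rods"`, `"isotropic_rods"`,
#'   or `"plates"`.
#' @param axis unit 3-vector, mean rod axis for `aligned_rods`.
#' @param scatter_deg von Mises--Fisher angular scatter (degrees).
#' @param rod_radius_um rod radius, µm.
#' @param target_fill trabecular volume fraction of the cavity, in (0,1).
#' @param plate_normal,plate_thickness_um,plate_spacing_um plate model
#'   geometry.
#' @param cavity_fill_extent `"full"` or `"open_midshaft"` (the middle
#'   third of the cavity is left open).
#' @param blur_sigma_vox,noise_sd_frac,bias_poly_degree imaging model:
#'   Gaussian blur (voxels), additive noise SD as a fraction of the
#'   bone/background contrast, multiplicative polynomial bias (+-10%).
#'   `noise_sd_frac = 0.2` corresponds to SNR 5.
#' @param spacing_um isotropic voxel spacing, µm.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(length_um = 6000, outer_radius_um = 1200,
                         cortical_thickness_um = 300,
                         trabecular_model = c("aligned_rods",
                                              "isotropic_rods",
                                              "plates", "none"),
                         axis = c(0, 0, 1), scatter_deg = 10,
                         rod_radius_um = 60, target_fill = 0.3,
                         plate_normal = c(0, 0, 1),
                         plate_thickness_um = 100, plate_spacing_um = 300,
                         cavity_fill_extent = c("full", "open_midshaft"),
                         blur_sigma_vox = 0.8, noise_sd_frac = 0.2,
                         bias_poly_degree = 0L, spacing_um = 25,
                         seed = 1L) {
  trabecular_model <- match.arg(trabecular_model)
  cavity_fill_extent <- match.arg(cavity_fill_extent)
  stopifnot(spacing_um > 0, length_um > 0,
            min(outer_radius_um) > cortical_thickness_um,
            target_fill > 0, target_fill < 1)
  structure(list(
    length_um = length_um, outer_radius_um = outer_radius_um,
    cortical_thickness_um = cortical_thickness_um,
    trabecular_model = trabecular_model,
    axis = axis / sqrt(sum(axis^2)), scatter_deg = scatter_deg,
    rod_radius_um = rod_radius_um, target_fill = target_fill,
    plate_normal = plate_normal / sqrt(sum(plate_normal^2)),
    plate_thickness_um = plate_thickness_um,
    plate_spacing_um = plate_spacing_um,
    cavity_fill_extent = cavity_fill_extent,
    blur_sigma_vox = blur_sigma_vox, noise_sd_frac = noise_sd_frac,
    bias_poly_degree = as.integer(bias_poly_degree),
    spacing_um = spacing_um, seed = as.integer(seed)
  ), class = "phantom_spec")
}

with_phantom_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# von Mises-Fisher sample about mu with concentration kappa
rvmf <- function(n, mu, kappa) {
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  th <- runif(n, 0, 2 * pi)
  # orthonormal frame
  p <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- p - sum(p * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2], mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(pmax(0, 1 - w^2))
  t(sapply(seq_len(n), function(i)
    w[i] * mu + s[i] * (cos(th[i]) * e1 + sin(th[i]) * e2)))
}

runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  th <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

#' Generate a synthetic long-bone µCT volume with ground truth
#'
#' Deterministic given the spec's seed. Bone voxels get intensity 200,
#' background and cavity 50; rods are placed by Poisson sampling of
#' centres with von Mises--Fisher (or uniform) axes until the target
#' cavity fill fraction is reached within 0.02; imaging noise (blur,
#' additive Gaussian noise, polynomial bias) is applied last.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([voxel_volume()]) and `truth` (a
#'   `ground_truth` list: `labels` ([label_volume()]), `orientation`
#'   (n_trab x 3 axes) + `orientation_index`, `true_tb_th_um`,
#'   `true_fill`, `true_compactness`).
#' @export
make_long_bone <- function(spec) {
  sp <- spec$spacing_um
  rmax <- max(spec$outer_radius_um)
  margin <- 4 * sp
  nx <- ny <- as.integer(ceiling(2 * (rmax + margin) / sp))
  nzb <- as.integer(ceiling(spec$length_um / sp))
  mz <- 8L                       # air beyond both bone ends, as in a scan
  nz <- nzb + 2L * mz
  d <- c(nx, ny, nz)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  z01 <- (seq_len(nzb) - 0.5) / nzb
  router <- if (length(spec$outer_radius_um) == 2L) {
    # sinusoidal profile, waist (minimum) at mid-length
    mid <- mean(spec$outer_radius_um); amp <- diff(spec$outer_radius_um) / 2
    mid - amp * cos(2 * pi * (z01 - 0.5))
  } else rep(spec$outer_radius_um, nzb)
  rinner <- router - spec$cortical_thickness_um
  xg <- (seq_len(nx) - cx) * sp
  yg <- (seq_len(ny) - cy) * sp
  r2 <- outer(xg^2, yg^2, `+`)
  lab <- array(0L, d)
  # ends are capped with solid bone (a long bone is closed by its
  # epiphyses); the medullary cavity is fully enclosed
  n_cap <- max(1L, as.integer(round(spec$cortical_thickness_um / sp)))
  for (kb in seq_len(nzb)) {
    sl <- matrix(0L, nx, ny)
    sl[r2 <= router[kb]^2] <- 1L
    if (kb > n_cap && kb <= nzb - n_cap) sl[r2 <= rinner[kb]^2] <- 3L
    lab[, , kb + mz] <- sl
  }
  ox <- numeric(length(lab)); oy <- numeric(length(lab)); oz <- numeric(length(lab))
  fill_region <- lab == 3L
  if (spec$cavity_fill_extent == "open_midshaft") {
    zidx <- slice.index(lab, 3)
    fill_region <- fill_region &
      (zidx <= mz + nzb / 3 | zidx >= mz + 2 * nzb / 3)
  }
  n_region <- sum(fill_region)
  truth_fill <- 0
  if (spec$trabecular_model %in% c("aligned_rods", "isotropic_rods") &&
      n_region > 0) {
    with_phantom_seed(spec$seed, {
      kappa <- 1 / (spec$scatter_deg * pi / 180)^2
      region_idx <- which(fill_region)
      r_vox <- spec$rod_radius_um / sp
      max_rods <- 5000L
      placed <- 0L
      painted <- 0L
      lab_v <- as.integer(lab)
      # restrict "from" painting to cavity inside the fill region: mark it
      lab_v[region_idx] <- 9L
      half_len <- (max(rinner) * 1.5) / sp
      for (i in seq_len(max_rods)) {
        if (painted / n_region >= spec$target_fill - 0.005) break
        p <- arrayInd(sample(region_idx, 1L), d)
        a <- if (spec$trabecular_model == "aligned_rods")
          as.numeric(rvmf(1, spec$axis, kappa)) else as.numeric(runif_sphere(1))
        p0 <- p - 1 + (-half_len) * a
        p1 <- p - 1 + half_len * a
        painted <- painted +
          cpp_paint_capsule(lab_v, d, p0, p1, r_vox, 9L, 2L, ox, oy, oz, a)
        placed <- placed + 1L
      }
      frac <- painted / n_region
      if (frac < spec$target_fill - 0.02)
        stop(sprintf(
          "target_fill %.2f unreachable (reached %.2f after %d rods)",
          spec$target_fill, frac, placed), call. = FALSE)
      lab_v[lab_v == 9L] <- 3L
      lab <- array(lab_v, d)
      truth_fill <- frac
    })
  } else if (spec$trabecular_model == "plates" && n_region > 0) {
    idx <- which(fill_region)
    co <- arrayInd(idx, d)
    w <- (co - 1) * sp
    proj <- as.numeric(w %*% spec$plate_normal)
    period <- spec$plate_spacing_um
    in_plate <- (proj %% period) < spec$plate_thickness_um
    lab[idx[in_plate]] <- 2L
    pn <- spec$plate_normal
    ox[idx[in_plate]] <- pn[1]; oy[idx[in_plate]] <- pn[2]
    oz[idx[in_plate]] <- pn[3]
    truth_fill <- mean(in_plate)
  }
  gray <- array(50, d)
  gray[lab == 1L | lab == 2L] <- 200
  vol <- voxel_volume(gray, sp)
  if (spec$blur_sigma_vox > 0 || spec$noise_sd_frac > 0 ||
      spec$bias_poly_degree > 0) {
    vol <- add_imaging_noise(vol, spec$blur_sigma_vox, spec$noise_sd_frac,
                             spec$bias_poly_degree, seed = spec$seed + 1L)
  }
  trab_idx <- which(lab == 2L)
  orientation <- cbind(ox[trab_idx], oy[trab_idx], oz[trab_idx])
  truth <- structure(list(
    labels = label_volume(lab, sp),
    orientation = orientation, orientation_index = trab_idx,
    true_tb_th_um = if (spec$trabecular_model %in%
                        c("aligned_rods", "isotropic_rods"))
      2 * spec$rod_radius_um else spec$plate_thickness_um,
    true_fill = truth_fill,
    true_compactness = phantom_compactness_curve(spec)
  ), class = "ground_truth")
  list(volume = vol, truth = truth)
}

# analytic midshaft radial compactness: fill fraction inside the
# endosteal radius, 1 within the cortex
phantom_compactness_curve <- function(spec, n = 101L) {
  router <- min(spec$outer_radius_um)
  rinner <- router - spec$cortical_thickness_um
  dd <- seq(0, 1, length.out = n)
  fill <- if (spec$trabecular_model == "none" ||
              spec$cavity_fill_extent == "open_midshaft") 0 else spec$target_fill
  comp <- ifelse(dd * router < rinner, fill, 1)
  data.frame(d = dd, compactness = comp)
}

#' Synthetic midshaft cross-section with analytic compactness
#'
#' An annulus (outer radius, cortical thickness) whose cavity is filled
#' with bone pixels at a Bernoulli `fill` fraction; the analytic radial
#' compactness curve is the step from `fill` to 1 at the endosteal
#' radius.
#'
#' @param outer_radius_um,cortical_thickness_um section geometry, µm.
#' @param fill cavity fill fraction in `[0, 1)` (0 = open cavity).
#' @param spacing_um pixel spacing, µm.
#' @param seed integer seed for the speckle fill.
#' @return list with `section` (logical matrix), `analytic`
#'   (data.frame `d`, `compactness`), `spacing_um`.
#' @export
make_cross_section <- function(outer_radius_um = 1500,
                               cortical_thickness_um = 400, fill = 0,
                               spacing_um = 20, seed = 1L) {
  sp <- spacing_um
  n <- as.integer(ceiling(2 * (outer_radius_um + 3 * sp) / sp))
  cen <- (n + 1) / 2
  g <- (seq_len(n) - cen) * sp
  r <- sqrt(outer(g^2, g^2, `+`))
  section <- r <= outer_radius_um
  rinner <- outer_radius_um - cortical_thickness_um
  cavity <- r <= rinner
  section[cavity] <- FALSE
  if (fill > 0) {
    with_phantom_seed(seed, {
      spk <- matrix(runif(n * n) < fill, n, n)
      section[cavity & spk] <- TRUE
    })
  }
  dd <- seq(0, 1, length.out = 101L)
  comp <- ifelse(dd * outer_radius_um < rinner, fill, 1)
  list(section = section, analytic = data.frame(d = dd, compactness = comp),
       spacing_um = sp)
}

#' Apply the imaging degradation model
#'
#' Gaussian blur, then additive Gaussian noise (SD expressed as a
#' fraction of the volume's intensity contrast), then a multiplicative
#' low-order polynomial bias field spanning +-10%. Deterministic given
#' the seed; all parameters zero is the identity.
#'
#' @param vol a [voxel_volume()].
#' @param blur_sigma Gaussian sigma, voxels.
#' @param gaussian_sd additive noise SD as a fraction of contrast.
#' @param bias_degree polynomial degree of the bias field (0 = none).
#' @param seed integer seed.
#' @return degraded [voxel_volume()].
#' @export
add_imaging_noise <- function(vol, blur_sigma = 0, gaussian_sd = 0,
                              bias_degree = 0L, seed = 1L) {
  stopifnot(blur_sigma >= 0, gaussian_sd >= 0, bias_degree >= 0)
  arr <- vol$data
  d <- dim(arr)
  contrast <- diff(range(arr))
  if (blur_sigma > 0)
    arr <- array(cpp_gauss3d(as.numeric(arr), d, blur_sigma, TRUE), d)
  with_phantom_seed(seed, {
    if (gaussian_sd > 0 && contrast > 0)
      arr <- arr + rnorm(length(arr), 0, gaussian_sd * contrast)
    if (bias_degree > 0) {
      expo <- poly_exponents(bias_degree)
      expo <- expo[rowSums(expo) > 0, , drop = FALSE]
      beta <- runif(nrow(expo), -1, 1)
      cx <- norm_coord(d[1]); cy <- norm_coord(d[2]); cz <- norm_coord(d[3])
      field <- array(0, d)
      for (m in seq_len(nrow(expo)))
        field <- field + beta[m] *
          outer(outer(cx^expo[m, 1], cy^expo[m, 2]), cz^expo[m, 3])
      amp <- max(abs(field))
      if (amp > 0) field <- field / amp * 0.1
      arr <- arr * (1 + field)
    }
  })
  with_data(vol, arr)
}

#' Cube of trabecular rods (fabric fixture)
#'
#' A plain cube filled with rods — no cortex — used to exercise the
#' fabric estimators directly against a known orientation distribution.
#'
#' @param edge_um cube edge, µm.
#' @param model `"aligned_rods"` or `"isotropic_rods"`.
#' @param axis,scatter_deg,rod_radius_um,target_fill as in
#'   [phantom_spec()].
#' @param spacing_um voxel spacing, µm.
#' @param seed integer seed.
#' @return list with `mask` (logical array), `label`
#'   (a [label_volume()] with rods = 2, space = 3), `axis`, `spacing_um`.
#' @export
make_rod_cube <- function(edge_um = 2000,
                          model = c("aligned_rods", "isotropic_rods"),
                          axis = c(0, 0, 1), scatter_deg = 10,
                          rod_radius_um = 80, target_fill = 0.3,
                          spacing_um = 40, seed = 1L) {
  model <- match.arg(model)
  sp <- spacing_um
  n <- as.integer(ceiling(edge_um / sp))
  d <- c(n, n, n)
  lab_v <- rep(9L, prod(d))
  ox <- numeric(prod(d)); oy <- numeric(prod(d)); oz <- numeric(prod(d))
  axis <- axis / sqrt(sum(axis^2))
  with_phantom_seed(seed, {
    kappa <- 1 / (scatter_deg * pi / 180)^2
    r_vox <- rod_radius_um / sp
    half_len <- n
    painted <- 0L
    for (i in seq_len(5000L)) {
      if (painted / prod(d) >= target_fill - 0.005) break
      p <- runif(3, 0, n - 1)
      a <- if (model == "aligned_rods") as.numeric(rvmf(1, axis, kappa))
           else as.numeric(runif_sphere(1))
      painted <- painted +
        cpp_paint_capsule(lab_v, d, p - half_len * a, p + half_len * a,
                          r_vox, 9L, 2L, ox, oy, oz, a)
    }
  })
  lab_v[lab_v == 9L] <- 3L
  lab <- array(lab_v, d)
  list(mask = lab == 2L, label = label_volume(lab, sp), axis = axis,
       spacing_um = sp)
}
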