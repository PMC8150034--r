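#' Build the spherical-neighbourhood sampling lattice
#'
#' Sample spacing `s` is 500 µm, or three times the average trabecular
#' width when that width exceeds 167 µm (the changeover point where
#' 3 x Tb.Th = 500 µm); the radius of influence equals the spacing, so
#' adjacent spherical neighbourhoods overlap by 50% of their diameter:
#' `(2r - s) / (2r) = 1/2` when `r = s`. Centres lie on a regular cubic
#' grid of step `s` anchored at the trabecular ROI bounding-box minimum
#' corner plus `s/2`, and only centres whose radius-`r` ball intersects
#' the ROI are kept.
#'
#' @param label a [label_volume()] with trabecular label 2.
#' @param tb_th_um average trabecular width, µm (e.g. from
#'   [local_thickness()]).
#' @param spacing_um,radius_um optional manual overrides of the lattice
#'   geometry (both µm); the adaptive rule is used when `NULL`.
#' @return a `sampling_lattice` list with `spacing`, `radius`, and
#'   `centres` (n x 3 world coordinates, µm).
#' @export
build_lattice <- function(label, tb_th_um, spacing_um = NULL,
                          radius_um = NULL) {
  if (is.null(spacing_um)) {
    if (!is.numeric(tb_th_um) || tb_th_um <= 0)
      stop("tb_th_um must be positive", call. = FALSE)
    spacing_um <- if (tb_th_um > 167) 3 * tb_th_um else 500
  }
  if (is.null(radius_um)) radius_um <- spacing_um
  sp <- label$spacing
  idx <- which(label$labels == 2L)
  if (length(idx) == 0L) stop("empty trabecular ROI", call. = FALSE)
  co <- arrayInd(idx, dim(label$labels)) - 1
  w <- index_to_world(label, co)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  grids <- lapply(1:3, function(a) {
    if (hi[a] - lo[a] < spacing_um / 2) return((lo[a] + hi[a]) / 2)
    seq(lo[a] + spacing_um / 2, hi[a], by = spacing_um)
  })
  centres <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  colnames(centres) <- c("x", "y", "z")
  # keep centres whose ball intersects the ROI (cheap distance check
  # against a subsample cap is avoided by gridding the ROI voxels)
  keep <- ball_intersects_roi(centres, w, radius_um)
  structure(list(spacing = spacing_um, radius = radius_um,
                 centres = centres[keep, , drop = FALSE]),
            class = "sampling_lattice")
}

# TRUE for each centre whose radius-r ball contains at least one ROI point.
ball_intersects_roi <- function(centres, pts, r) {
  cell <- r
  key <- function(m) paste(floor(m[, 1] / cell), floor(m[, 2] / cell),
                           floor(m[, 3] / cell))
  pk <- split(seq_len(nrow(pts)), key(pts))
  vapply(seq_len(nrow(centres)), function(i) {
    c0 <- floor(centres[i, ] / cell)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(c0[1] + dx, c0[2] + dy, c0[3] + dz)
      ids <- pk[[k]]
      if (is.null(ids)) next
      dd <- sweep(pts[ids, , drop = FALSE], 2, centres[i, ])
      if (any(rowSums(dd^2) <= r^2)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Surface normals of a binary structure
#'
#' Normals are the normalized gradient (central differences) of the
#' Gaussian-smoothed (sigma 1 voxel) binary mask, evaluated at surface
#' voxels — structure voxels with at least one 6-connected background
#' neighbour. Voxels with gradient magnitude below 1e-6 are skipped.
#'
#' @param mask logical 3D array.
#' @param spacing isotropic voxel spacing, µm.
#' @param origin world origin, µm.
#' @return list with `points` (n x 3 world coordinates, µm) and
#'   `normals` (n x 3 unit vectors); zero rows when no surface exists.
#' @export
surface_normals <- function(mask, spacing, origin = c(0, 0, 0)) {
  d <- dim(mask)
  sp <- spacing[1]
  sm <- array(cpp_gauss3d(as.numeric(mask), d, 1.0, TRUE), d)
  surf <- surface_voxels(mask)
  idx <- which(surf)
  if (length(idx) == 0L)
    return(list(points = matrix(0, 0, 3), normals = matrix(0, 0, 3)))
  co <- arrayInd(idx, d)
  g <- gradient_at(sm, co)
  mag <- sqrt(rowSums(g^2))
  ok <- mag > 1e-6
  co <- co[ok, , drop = FALSE]
  g <- g[ok, , drop = FALSE] / mag[ok]
  list(points = index_to_world(list(spacing = rep(sp, 3), origin = origin),
                               co - 1),
       normals = g)
}

surface_voxels <- function(mask) {
  d <- dim(mask)
  pad <- function(shift_axis, dir) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    n <- d[shift_axis]
    if (dir > 0) { dst[[shift_axis]] <- 1:(n - 1); src[[shift_axis]] <- 2:n }
    else { dst[[shift_axis]] <- 2:n; src[[shift_axis]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- !mask[src[[1]], src[[2]], src[[3]]]
    # grid border counts as background
    brd <- lapply(d, seq_len)
    brd[[shift_axis]] <- if (dir > 0) n else 1L
    out[brd[[1]], brd[[2]], brd[[3]]] <- TRUE
    out
  }
  nb_bg <- pad(1, 1) | pad(1, -1) | pad(2, 1) | pad(2, -1) |
    pad(3, 1) | pad(3, -1)
  mask & nb_bg
}

gradient_at <- function(arr, co) {
  d <- dim(arr)
  comp <- function(axis) {
    hi <- co; hi[, axis] <- pmin(co[, axis] + 1L, d[axis])
    lo <- co; lo[, axis] <- pmax(co[, axis] - 1L, 1L)
    (arr[hi] - arr[lo]) / pmax(hi[, axis] - lo[, axis], 1L)
  }
  cbind(comp(1), comp(2), comp(3))
}

#' Fabric tensor from a set of surface normals
#'
#' The orientation tensor is the mean outer product of the unit normals,
#' trace-normalized to 1. The degree of anisotropy is
#' `da = 1 - lambda_min / lambda_max`; the principal material axis is the
#' eigenvector of the smallest eigenvalue (the direction the normals
#' avoid, i.e. the long axis of the struts), reported sign-free with a
#' non-negative slice-axis component. Samples built from fewer than
#' `min_count` normals are undefined and carry the sentinel `da = 0`;
#' plate-like distributions where the two smallest eigenvalues nearly
#' coincide (`(lambda2 - lambda3)/lambda1 < 0.05`) set `degenerate`.
#'
#' @param normals n x 3 matrix of unit vectors.
#' @param min_count minimum normals for a defined sample (default 50).
#' @return list with `eigenvalues` (descending, sum 1), `axis`, `da`,
#'   `n_normals`, `degenerate`, `defined`.
#' @export
fabric_tensor <- function(normals, min_count = 50L) {
  n <- nrow(normals)
  if (is.null(n) || n < min_count) {
    return(list(eigenvalues = rep(NA_real_, 3), axis = c(NA, NA, NA),
                da = 0, n_normals = if (is.null(n)) 0L else n,
                degenerate = FALSE, defined = FALSE))
  }
  C <- crossprod(normals) / n
  C <- C / sum(diag(C))
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  axis <- eg$vectors[, 3]
  axis <- fix_axis_sign(axis)
  da <- 1 - max(ev[3], 0) / ev[1]
  list(eigenvalues = ev, axis = axis, da = da, n_normals = n,
       degenerate = (ev[2] - ev[3]) / ev[1] < 0.05, defined = TRUE)
}

fix_axis_sign <- function(a) {
  s <- if (abs(a[3]) > 1e-12) sign(a[3])
       else if (abs(a[1]) > 1e-12) sign(a[1])
       else sign(a[2])
  a * ifelse(s == 0, 1, s)
}

#' Map trabecular anisotropy over the whole bone
#'
#' For each lattice centre, collects the surface normals of trabecular
#' voxels within the radius of influence and computes the fabric sample.
#' Centres with fewer than `min_normals` normals carry the scalar-map
#' zero convention (`da = 0`, undefined); zero values are discarded
#' before any histogram statistics.
#'
#' @param label a denoised [label_volume()].
#' @param lattice a [build_lattice()] result.
#' @param min_normals minimum normals per ball (default 50).
#' @return an `anisotropy_field` with `samples` (data.frame: `x, y, z,
#'   da, ax, ay, az, n_normals, degenerate, defined`), `lattice`, and the
#'   per-sample eigenvalue matrix.
#' @export
map_anisotropy <- function(label, lattice, min_normals = 50L) {
  sn <- surface_normals(label$labels == 2L, label$spacing, label$origin)
  cs <- lattice$centres
  r <- lattice$radius
  n <- nrow(cs)
  # grid the normals for ball queries
  cell <- r
  key3 <- function(m) paste(floor(m[, 1] / cell), floor(m[, 2] / cell),
                            floor(m[, 3] / cell))
  pk <- if (nrow(sn$points)) split(seq_len(nrow(sn$points)), key3(sn$points))
        else list()
  samples <- data.frame(
    x = cs[, 1], y = cs[, 2], z = cs[, 3], da = 0,
    ax = NA_real_, ay = NA_real_, az = NA_real_,
    n_normals = 0L, degenerate = FALSE, defined = FALSE
  )
  evals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    c0 <- floor(cs[i, ] / cell)
    ids <- integer()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(c0[1] + dx, c0[2] + dy, c0[3] + dz)
      if (!is.null(pk[[k]])) ids <- c(ids, pk[[k]])
    }
    if (length(ids)) {
      dd <- sweep(sn$points[ids, , drop = FALSE], 2, cs[i, ])
      ids <- ids[rowSums(dd^2) <= r^2]
    }
    ft <- fabric_tensor(sn$normals[ids, , drop = FALSE], min_normals)
    samples$da[i] <- ft$da
    samples$n_normals[i] <- ft$n_normals
    samples$degenerate[i] <- ft$degenerate
    samples$defined[i] <- ft$defined
    if (ft$defined) {
      samples[i, c("ax", "ay", "az")] <- as.list(ft$axis)
      evals[i, ] <- ft$eigenvalues
    }
  }
  structure(list(samples = samples, lattice = lattice, eigenvalues = evals),
            class = "anisotropy_field")
}

#' @export
print.anisotropy_field <- function(x, ...) {
  cat(sprintf("<anisotropy_field> %d samples (%d defined), lattice s = r = %g µm\n",
              nrow(x$samples), sum(x$samples$defined), x$lattice$spacing))
  invisible(x)
}

#' Zero-excluded degree-of-anisotropy histogram
#'
#' Undefined samples carry the sentinel value 0 in the scalar map and
#' must be discarded before binning; the mode (`Ani.M`) is the centre of
#' the maximum-count bin, ties resolved toward the lower bin.
#'
#' @param field an `anisotropy_field`.
#' @param bin_width bin width on `[0, 1]` (default 0.05).
#' @return a `da_histogram` list with `breaks`, `counts`, `mode`
#'   (`Ani.M`; `NA` when no defined samples), `n_defined`.
#' @export
da_histogram <- function(field, bin_width = 0.05) {
  da <- field$samples$da[field$samples$defined & field$samples$da > 0]
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-9) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  counts <- integer(nb)
  if (length(da)) {
    bin <- pmin(nb, as.integer(da / bin_width) + 1L)
    counts <- tabulate(bin, nbins = nb)
  }
  mode <- if (length(da)) {
    k <- which.max(counts)  # which.max takes the first (lower) tie
    (breaks[k] + breaks[k + 1]) / 2
  } else NA_real_
  structure(list(breaks = breaks, counts = counts, mode = mode,
                 bin_width = bin_width, n_defined = length(da)),
            class = "da_histogram")
}

#' Keep only high-anisotropy samples
#'
#' Retains defined samples with `da >= threshold` (boundary inclusive),
#' preserving order and geometry; the default threshold of 0.65 matches
#' the high-anisotropy vector maps.
#'
#' @param field an `anisotropy_field`.
#' @param threshold inclusive lower bound (default 0.65).
#' @return an `anisotropy_field` subset.
#' @export
filter_high <- function(field, threshold = 0.65) {
  keep <- field$samples$defined & field$samples$da >= threshold
  structure(list(samples = field$samples[keep, , drop = FALSE],
                 lattice = field$lattice,
                 eigenvalues = field$eigenvalues[keep, , drop = FALSE]),
            class = "anisotropy_field")
}

#' Axial alignment coherence per long-axis region
#'
#' Quantifies how mutually aligned the (sign-free) principal axes of the
#' retained samples are within regions along the long axis:
#' `coherence = (3 eta1 - 1) / 2` where `eta1` is the largest eigenvalue
#' of the mean outer-product tensor of the axes — 0 for uniformly random
#' axes, 1 for perfect alignment. Regions with fewer than 5 samples are
#' reported as undefined.
#'
#' @param field an `anisotropy_field` (typically from [filter_high()]).
#' @param n_regions number of equal-extent regions along the slice axis
#'   (default 3: proximal, mid, distal thirds).
#' @return data.frame with `region`, `z_min`, `z_max`, `coherence`,
#'   `n_samples`.
#' @export
coherence <- function(field, n_regions = 3L) {
  s <- field$samples[field$samples$defined, , drop = FALSE]
  zr <- if (nrow(s)) range(s$z) else c(0, 1)
  brk <- seq(zr[1], zr[2], length.out = n_regions + 1L)
  brk[length(brk)] <- brk[length(brk)] + 1e-9
  out <- data.frame(region = seq_len(n_regions),
                    z_min = brk[-length(brk)], z_max = brk[-1],
                    coherence = NA_real_, n_samples = 0L)
  for (g in seq_len(n_regions)) {
    in_g <- s$z >= brk[g] & s$z < brk[g + 1]
    out$n_samples[g] <- sum(in_g)
    if (sum(in_g) < 5L) next
    A <- as.matrix(s[in_g, c("ax", "ay", "az")])
    M <- crossprod(A) / nrow(A)
    eta1 <- eigen(M, symmetric = TRUE, only.values = TRUE)$values[1]
    out$coherence[g] <- (3 * eta1 - 1) / 2
  }
  out
}

# quasi-uniform sign-free directions (Fibonacci hemisphere)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n            # upper hemisphere only: axes are sign-free
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Mean-intercept-length fabric (independent estimator)
#'
#' Classic MIL fabric analysis over parallel line probes: for each of
#' `n_directions` quasi-uniform directions, the probes crossing the mask
#' count bone/background interfaces, giving
#' `MIL = 2 * bone length / crossings`. The MIL ellipsoid is fitted by
#' least squares on `1/MIL^2 = n' M n`; the principal axis is the longest
#' MIL direction and `da = 1 - MIL_min / MIL_max`, defined analogously to
#' the surface-normal estimator. Serves as an in-package cross-check of
#' the normal-covariance fabric.
#'
#' @param mask logical 3D array (structure within the ball/region).
#' @param spacing isotropic voxel spacing, µm.
#' @param n_directions number of probe directions (default 128).
#' @param probe_step step along each probe, voxels (default 0.5).
#' @return list with `mil` (per-direction), `directions`, `eigenvalues`
#'   of the MIL tensor, `axis`, `da`.
#' @export
mil_fabric <- function(mask, spacing, n_directions = 128L, probe_step = 0.5) {
  d <- dim(mask)
  dirs <- fibonacci_directions(n_directions)
  cen <- (d + 1) / 2
  R <- sqrt(sum(((d - 1) / 2)^2))
  mil <- rep(NA_real_, n_directions)
  for (k in seq_len(n_directions)) {
    u <- dirs[k, ]
    # orthonormal frame for probe offsets
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- p - sum(p * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    off <- as.matrix(expand.grid(a = seq(-R, R, by = 2), b = seq(-R, R, by = 2)))
    off <- off[rowSums(off^2) <= R^2, , drop = FALSE]
    tt <- seq(-R, R, by = probe_step)
    # sample all probes at once: n_probe x n_step occupancy matrix
    base <- off %*% rbind(e1, e2)
    occ <- matrix(FALSE, nrow(off), length(tt))
    for (j in seq_along(tt)) {
      pos <- sweep(base + tt[j] * matrix(u, nrow(off), 3, byrow = TRUE),
                   2, cen, `+`)
      ijk <- round(pos)
      ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 &
        ijk[, 2] <= d[2] & ijk[, 3] >= 1 & ijk[, 3] <= d[3]
      v <- rep(FALSE, nrow(off))
      if (any(ok)) v[ok] <- mask[ijk[ok, , drop = FALSE]]
      occ[, j] <- v
    }
    crossings <- sum(abs(occ[, -1, drop = FALSE] - occ[, -ncol(occ), drop = FALSE]))
    bone_len <- sum(occ) * probe_step
    if (crossings >= 2) mil[k] <- 2 * bone_len / crossings
  }
  ok <- !is.na(mil) & mil > 0
  if (sum(ok) < 9L)
    stop("fewer than 9 usable probe directions", call. = FALSE)
  n <- dirs[ok, , drop = FALSE]
  X <- cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
             2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
  b <- 1 / mil[ok]^2
  m <- lm.fit(X, b)$coefficients
  M <- matrix(c(m[1], m[4], m[5], m[4], m[2], m[6], m[5], m[6], m[3]), 3, 3)
  eg <- eigen(M, symmetric = TRUE)
  ev <- pmax(eg$values, 1e-12)
  lens <- 1 / sqrt(ev)          # MIL semi-axes; longest = smallest eigenvalue
  axis <- fix_axis_sign(eg$vectors[, 3])
  da <- 1 - min(lens) / max(lens)
  list(mil = mil, directions = dirs, eigenvalues = ev, axis = axis, da = da)
}
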