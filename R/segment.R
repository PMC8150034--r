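# Morphology on binary arrays via the exact Euclidean distance transform;
# radii in voxel units, structuring element = Euclidean ball.

dilate_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  d2 <- cpp_edt_sq(as.logical(mask), dim(mask))
  array(d2 <= r * r + 1e-9, dim(mask))
}

erode_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  d2 <- cpp_edt_sq(!as.logical(mask), dim(mask))
  array(d2 > r * r + 1e-9, dim(mask)) & mask
}

# Closing pads the grid with background first: structures touching the
# array border must behave as if surrounded by air, or the erosion step
# (which treats out-of-bounds as foreground) welds them to the border.
close_ball <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- dim(mask)
  p <- as.integer(ceiling(r) + 1L)
  dp <- d + 2L * p
  big <- array(FALSE, dp)
  big[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- mask
  big <- erode_ball(dilate_ball(big, r), r)
  big[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

# Per-slice 2D hole filling (4-connectivity in-plane): catches medullary
# cavities that open onto the proximal/distal grid faces, e.g. in
# fragmentary elements cut by the scan boundary.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- array(mask[, , k], c(d[1], d[2], 1L))
    lab <- array(cpp_label3d(!as.logical(sl), dim(sl), 6L), dim(sl))
    border <- unique(c(lab[c(1, d[1]), , 1], lab[, c(1, d[2]), 1]))
    border <- border[border > 0]
    out[, , k] <- sl[, , 1] | (lab[, , 1] > 0 & !(lab[, , 1] %in% border))
  }
  out
}

# Fill internal background cavities: background components (6-connected)
# not touching the grid border become foreground.
fill_holes3d <- function(mask) {
  d <- dim(mask)
  lab <- array(cpp_label3d(!as.logical(mask), d, 6L), d)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

#' Segmentation configuration
#'
#' @param shell_closing_radius_um radius of the morphological closing that
#'   defines the periosteal surface, µm; default 5 voxels at the volume's
#'   spacing (resolved at run time when `NULL`).
#' @param cortical_thickness_um optional fixed cortical wall thickness,
#'   µm; when `NULL` (default) the wall thickness is estimated per slice
#'   from the local thickness of the bone at the periosteal surface.
#' @param min_component minimum connected trabecular component, voxels.
#' @param axis_align rotate the long axis onto the slice axis first?
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(shell_closing_radius_um = NULL,
                                cortical_thickness_um = NULL,
                                min_component = 27L, axis_align = TRUE) {
  if (min_component < 1L) stop("min_component must be >= 1", call. = FALSE)
  structure(list(shell_closing_radius_um = shell_closing_radius_um,
                 cortical_thickness_um = cortical_thickness_um,
                 min_component = as.integer(min_component),
                 axis_align = isTRUE(axis_align)),
            class = "segmentation_config")
}

#' Align the bone's long axis with the slice axis
#'
#' Rotates the volume so the principal inertia axis of the bone mask maps
#' onto the third (slice) axis. Nearly isotropic (spherical) masks fall
#' back to the identity with `degenerate = TRUE`. Masks are resampled
#' nearest-neighbour, grayscale volumes trilinearly.
#'
#' @param mask logical 3D array (bone mask).
#' @param spacing voxel spacing, µm (isotropic).
#' @param grayscale optional [voxel_volume()] rotated with the same
#'   transform.
#' @return list with `mask`, `grayscale` (or `NULL`), `rotation` (3x3,
#'   world frame), `angle_deg` (rotation applied), and `degenerate`.
#' @export
align_long_axis <- function(mask, spacing, grayscale = NULL) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  co <- arrayInd(idx, d) - 1
  cen <- colMeans(co)
  cv <- stats::cov(co)
  eg <- eigen(cv, symmetric = TRUE)
  degenerate <- (eg$values[1] - eg$values[2]) / eg$values[1] < 0.02
  v1 <- eg$vectors[, 1]
  if (v1[3] < 0) v1 <- -v1
  angle <- acos(min(1, abs(v1[3]))) * 180 / pi
  if (degenerate || angle < 1) {
    return(list(mask = mask, grayscale = grayscale, rotation = diag(3),
                angle_deg = 0, degenerate = degenerate))
  }
  # rotation taking v1 -> e3 (Rodrigues about v1 x e3)
  R <- rotation_between(v1, c(0, 0, 1))
  # output grid sized to contain the rotated bounding box
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  rot_corners <- t(R %*% (t(corners) - cen))
  lo <- floor(apply(rot_corners, 2, min))
  hi <- ceiling(apply(rot_corners, 2, max))
  outdim <- as.integer(hi - lo + 1)
  # pull-back: source = R^T (out + lo) + cen
  A <- t(R)
  tvec <- as.numeric(A %*% lo + cen)
  rmask <- cpp_resample_affine(as.numeric(mask), d, A, tvec, outdim,
                               nearest = TRUE, fill = 0)
  rmask <- array(rmask > 0.5, outdim)
  rgray <- NULL
  if (!is.null(grayscale)) {
    rg <- cpp_resample_affine(as.numeric(grayscale$data), dim(grayscale$data),
                              A, tvec, outdim, nearest = FALSE,
                              fill = min(grayscale$data))
    rgray <- voxel_volume(array(rg, outdim), spacing)
  }
  list(mask = rmask, grayscale = rgray, rotation = R, angle_deg = angle,
       degenerate = FALSE)
}

rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Segment cortical / trabecular / cavity compartments
#'
#' Dual-surface scheme. The periosteal envelope ("whole bone") is the
#' morphological closing of the bone mask with its internal cavities
#' filled. The cortical compartment is the bone lying within the local
#' wall thickness of the periosteal surface: a depth map inside the
#' envelope is compared against a per-slice estimate of the cortical
#' wall thickness (the median local thickness of the bone voxels at the
#' periosteal surface, median-smoothed along the bone). Bone deeper than
#' the wall is trabecular (label 2); non-bone voxels inside the envelope
#' are internal space (label 3). Cortical and trabecular labels together
#' reproduce the input bone mask exactly.
#'
#' @param bone_mask logical 3D array from [threshold_bone()].
#' @param spacing isotropic voxel spacing, µm.
#' @param config a [segmentation_config()].
#' @return a [label_volume()] with attribute `qc` (fractions and the
#'   wall-thickness profile used).
#' @export
segment_compartments <- function(bone_mask, spacing,
                                 config = segmentation_config()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (diff(range(spacing)) > 1e-6 * mean(spacing))
    stop("segment_compartments requires isotropic spacing", call. = FALSE)
  sp <- spacing[1]
  if (!any(bone_mask)) stop("empty bone mask", call. = FALSE)
  r_um <- config$shell_closing_radius_um
  if (is.null(r_um)) r_um <- 5 * sp
  r_vox <- r_um / sp
  d <- dim(bone_mask)

  closed <- close_ball(bone_mask, r_vox)
  whole <- fill_holes3d(closed) | fill_holes_slicewise(closed)
  # depth below the periosteal bone surface, voxels: measured from the
  # exterior air.  The closing may overshoot the bone by a voxel or two,
  # so the exterior is the complement of the envelope plus the non-bone
  # rim right under it (but never deeper, or noise pores would leak the
  # exterior into the medullary space)
  exterior <- !whole | (dilate_ball(!whole, 2.5) & !bone_mask)
  depth <- array(sqrt(cpp_edt_sq(exterior, d)), d)

  if (is.null(config$cortical_thickness_um)) {
    # wall thickness per slice: local thickness (pores plugged) of the
    # bone found right at the periosteal surface
    solid <- close_ball(bone_mask, 1)
    th <- array(cpp_local_thickness(as.logical(solid), d), d)
    shell <- bone_mask & depth <= 2
    ct_vox <- rep(NA_real_, d[3])
    for (k in seq_len(d[3])) {
      sel <- shell[, , k]
      if (any(sel)) ct_vox[k] <- median(th[, , k][sel])
    }
    ct_vox <- smooth_profile(ct_vox, 11L)
  } else {
    ct_vox <- rep(config$cortical_thickness_um / sp, d[3])
  }
  ct_arr <- array(rep(ct_vox, each = d[1] * d[2]), d)

  lab <- array(0L, d)
  lab[whole & !bone_mask] <- 3L
  lab[bone_mask] <- 1L
  # the wall-thickness estimate (2 x EDT) already carries a ~half-voxel
  # overshoot at the periosteal surface, so only a quarter-voxel guard is
  # needed to keep the endosteal bone surface cortical
  lab[bone_mask & depth > ct_arr + 0.25] <- 2L

  out <- label_volume(lab, sp)
  frac <- tabulate(lab + 1L, nbins = 4L) / length(lab)
  attr(out, "qc") <- list(
    shell_closing_radius_um = r_um,
    wall_thickness_um = ct_vox * sp,
    label_fractions = setNames(frac, c("air", "cortical", "trabecular", "cavity"))
  )
  out
}

# running-median smoothing of a per-slice profile with NA passthrough
smooth_profile <- function(x, window = 11L) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  # carry nearest defined value into NA gaps first
  filled <- x
  filled[is.na(x)] <- x[ok][findInterval(which(is.na(x)), ok,
                                         all.inside = TRUE)]
  h <- window %/% 2L
  out <- vapply(seq_along(filled), function(i) {
    median(filled[max(1, i - h):min(length(filled), i + h)])
  }, numeric(1))
  out
}

#' Whole-bone mask
#'
#' The union of cortical, trabecular, and internal-space labels; equals
#' the filled periosteal volume.
#'
#' @param label a [label_volume()].
#' @return logical 3D array.
#' @export
whole_bone_mask <- function(label) {
  array(label$labels > 0L, dim(label$labels))
}

#' Remove small trabecular components (multi-ROI denoising)
#'
#' 26-connected components of the trabecular label smaller than
#' `min_component` voxels are reassigned to the internal-space label;
#' all other labels are untouched, so the total voxel count is conserved.
#'
#' @param label a [label_volume()].
#' @param min_component minimum component size, voxels.
#' @return a [label_volume()].
#' @export
denoise_trabecular <- function(label, min_component = 27L) {
  if (min_component < 1L) stop("min_component must be >= 1", call. = FALSE)
  lab <- label$labels
  d <- dim(lab)
  cc <- array(cpp_label3d(lab == 2L, d, 26L), d)
  if (max(cc) > 0L) {
    sizes <- tabulate(cc[cc > 0L])
    small <- which(sizes < min_component)
    if (length(small)) lab[cc %in% small] <- 3L
  }
  out <- label_volume(lab, label$spacing, label$origin)
  attr(out, "qc") <- attr(label, "qc")
  out
}

# Crofton-style perimeter of a 2D binary mask: Cauchy's formula with
# boundary-crossing counts along 0/90/45/135 degree line families.
crofton_perimeter <- function(mask2d, spacing = 1) {
  m <- mask2d * 1L
  if (!any(m > 0)) return(0)
  n0 <- sum(abs(diff(m)) > 0) + sum(m[1, ] > 0) + sum(m[nrow(m), ] > 0)
  n90 <- sum(abs(t(diff(t(m)))) > 0) + sum(m[, 1] > 0) + sum(m[, ncol(m)] > 0)
  diag_cross <- function(m, anti = FALSE) {
    if (anti) m <- m[nrow(m):1, , drop = FALSE]
    nr <- nrow(m); nc <- ncol(m)
    tot <- 0
    for (off in (-(nr - 1)):(nc - 1)) {
      i <- seq_len(nr)
      j <- i + off
      ok <- j >= 1 & j <= nc
      v <- m[cbind(i[ok], j[ok])]
      if (length(v) == 0) next
      tot <- tot + sum(abs(diff(v)) > 0) + (v[1] > 0) + (v[length(v)] > 0)
    }
    tot
  }
  n45 <- diag_cross(m)
  n135 <- diag_cross(m, anti = TRUE)
  # width_theta = N_theta * h_theta / 2 with h = 1 (axes), 1/sqrt(2) (diagonals)
  widths <- c(n0, n90, n45 / sqrt(2), n135 / sqrt(2)) / 2
  pi * mean(widths) * spacing
}

#' Locate the midshaft slice
#'
#' Computes the per-slice outer perimeter of the whole-bone mask with a
#' Crofton-style estimator; the search window is the contiguous run of
#' slices within 2% of the minimum perimeter containing the argmin, and
#' the midshaft is the slice of maximum cortical area within that window
#' (ties resolved toward the window centre).
#'
#' @param label an axis-aligned [label_volume()] with at least 10 slices.
#' @return a `midshaft_selection` list with `slice_index` (1-based),
#'   `circumference_profile` (mm), `cortical_area_profile` (mm^2), and
#'   `search_window`.
#' @export
find_midshaft <- function(label) {
  d <- dim(label$labels)
  if (d[3] < 10L) stop("need at least 10 slices", call. = FALSE)
  sp <- require_isotropic(label, "find_midshaft")
  whole <- whole_bone_mask(label)
  has_bone <- apply(label$labels == 1L | label$labels == 2L, 3, any)
  if (!any(has_bone)) stop("no bone in any slice", call. = FALSE)
  # the midshaft lies in the central diaphysis: restrict the perimeter
  # search to 25--75% of the occupied extent so end caps, epiphyses, and
  # stray fringe voxels cannot capture the minimum
  occ <- which(apply(whole, 3, any))
  zlo <- occ[1] + floor(0.25 * (length(occ) - 1))
  zhi <- occ[1] + ceiling(0.75 * (length(occ) - 1))
  perim <- rep(NA_real_, d[3])
  ct_ar <- rep(0, d[3])
  for (k in intersect(zlo:zhi, which(apply(whole, 3, any)))) {
    filled <- fill_holes3d(array(whole[, , k], c(d[1], d[2], 1)))[, , 1]
    perim[k] <- crofton_perimeter(filled, sp) / 1000  # mm
    ct_ar[k] <- sum(label$labels[, , k] == 1L) * sp^2 / 1e6  # mm^2
  }
  ok <- which(!is.na(perim) & perim > 0)
  pmin_ <- min(perim[ok])
  within <- !is.na(perim) & perim <= pmin_ * 1.02
  argmin <- ok[which.min(perim[ok])]
  runs <- rle(within)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ri <- which(starts <= argmin & ends >= argmin & runs$values)
  window <- starts[ri]:ends[ri]
  best <- max(ct_ar[window])
  cand <- window[ct_ar[window] >= best - 1e-12]
  centre <- mean(range(window))
  slice <- cand[which.min(abs(cand - centre))]
  structure(list(slice_index = slice,
                 circumference_profile = perim,
                 cortical_area_profile = ct_ar,
                 search_window = window),
            class = "midshaft_selection")
}

#' Full segmentation driver
#'
#' Threshold, optional long-axis alignment, compartment segmentation, and
#' trabecular denoising, in order.
#'
#' @param vol a preprocessed [voxel_volume()] (isotropic).
#' @param config a [segmentation_config()].
#' @param threshold_method,fixed passed to [threshold_bone()].
#' @return list with `label` ([label_volume()]), `alignment`, and `mask`.
#' @export
segment_volume <- function(vol, config = segmentation_config(),
                           threshold_method = "otsu", fixed = NULL) {
  sp <- require_isotropic(vol, "segment_volume")
  mask <- threshold_bone(vol, threshold_method, fixed)
  # noise voxels above threshold form tiny components; drop them before
  # any morphology so the closing cannot weld them into the bone
  cc <- array(cpp_label3d(as.logical(mask), dim(mask), 26L), dim(mask))
  if (max(cc) > 0L) {
    sizes <- tabulate(cc[cc > 0L])
    keep <- which(sizes >= config$min_component)
    mask <- array(cc %in% keep, dim(mask))
  }
  alignment <- NULL
  if (config$axis_align) {
    alignment <- align_long_axis(mask, sp, grayscale = vol)
    mask <- alignment$mask
  }
  lab <- segment_compartments(mask, sp, config)
  lab <- denoise_trabecular(lab, config$min_component)
  list(label = lab, alignment = alignment, mask = mask)
}
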