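#' Voxel volume container
#'
#' A 3D grayscale grid with physical geometry. Voxel `(i, j, k)` (0-based)
#' has world coordinates `origin + c(i, j, k) * spacing` (voxel-centre
#' convention); the third array axis (`k`) is the slice axis, and after
#' long-axis alignment it coincides with the anatomical proximo-distal axis.
#'
#' @param data numeric 3D array of intensities (arbitrary units).
#' @param spacing per-axis voxel edge length in micrometres (length 1 or 3).
#' @param origin world coordinate (micrometres) of the centre of voxel
#'   `(0, 0, 0)`.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values in µm", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %s µm, range [%g, %g]\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Label volume: compartment labels on a voxel grid
#'
#' Shares geometry with the source [voxel_volume()]. Labelling scheme:
#' 0 = air/background, 1 = cortical bone, 2 = trabecular bone,
#' 3 = internal non-bone space (medullary cavity / marrow / pore space).
#'
#' @param labels integer 3D array with values in `0:3`.
#' @param spacing,origin geometry, as for [voxel_volume()].
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  stopifnot(length(dim(labels)) == 3L)
  if (!all(labels %in% 0:3))
    stop("labels must be integers in 0:3", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(
    list(labels = array(as.integer(labels), dim(labels)),
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels, spacing %s µm\n  air %d | cortical %d | trabecular %d | cavity %d\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    tab[1], tab[2], tab[3], tab[4]
  ))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Convert between voxel indices and world coordinates
#'
#' Indices are 0-based, world coordinates in micrometres, voxel-centre
#' convention. The two functions are mutual inverses for in-grid points.
#'
#' @param geom a `voxel_volume` or `label_volume` (anything with `spacing`
#'   and `origin`).
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @param xyz n x 3 matrix of world coordinates, micrometres.
#' @return an n x 3 numeric matrix.
#' @export
index_to_world <- function(geom, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, geom$spacing, `*`), 2, geom$origin, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(geom, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, geom$origin, `-`), 2, geom$spacing, `/`)
}

# geometry equality check shared by several modules
same_geometry <- function(a, b, tol = 1e-9) {
  da <- if (!is.null(a$data)) dim(a$data) else dim(a$labels)
  db <- if (!is.null(b$data)) dim(b$data) else dim(b$labels)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

require_isotropic <- function(x, what = "this operation") {
  if (diff(range(x$spacing)) > 1e-6 * mean(x$spacing))
    stop(sprintf("%s requires isotropic voxel spacing; call resample_isotropic() first",
                 what), call. = FALSE)
  invisible(x$spacing[1])
}
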