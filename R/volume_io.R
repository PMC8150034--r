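#' Read a µCT volume from disk
#'
#' Supports NRRD (attached raw encoding), MHD/RAW headers, multi-page TIFF
#' files, and directories of single-slice TIFF files (slices taken in
#' lexicographic filename order). Intensities are returned exactly as
#' stored, without rescaling; 8/16-bit integer and 32/64-bit float data
#' are accepted. TIFF stores no physical spacing, so `spacing_override`
#' is required there; for NRRD/MHD it replaces the stored spacing when
#' given.
#'
#' @param path file (NRRD, MHD, multi-page TIFF) or directory of TIFF
#'   slices.
#' @param spacing_override optional per-axis voxel spacing in µm (length 1
#'   or 3).
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path))
    stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("directory contains no TIFF slices", call. = FALSE)
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    return(stack_to_volume(slices, spacing_override))
  }
  ext <- tolower(tools::file_ext(path))
  vol <- switch(ext,
    nrrd = read_nrrd(path),
    mhd = read_mhd(path),
    tif = ,
    tiff = {
      slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(slices)) slices <- list(slices)
      stack_to_volume(slices, spacing_override)
    },
    stop(sprintf("unsupported volume format: .%s", ext), call. = FALSE)
  )
  if (!is.null(spacing_override)) {
    if (length(spacing_override) == 1L) spacing_override <- rep(spacing_override, 3)
    vol$spacing <- as.numeric(spacing_override)
  }
  vol
}

stack_to_volume <- function(slices, spacing_override) {
  dims <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions in TIFF stack", call. = FALSE)
  if (is.null(spacing_override))
    stop("TIFF stores no voxel spacing; supply `spacing_override` (µm)",
         call. = FALSE)
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  voxel_volume(arr, spacing_override)
}

#' Write a volume or label map to disk
#'
#' NRRD (attached raw, little-endian) and MHD+RAW are supported; label
#' maps are written as unsigned 8-bit, grayscale as 32-bit float unless
#' `dtype` says otherwise.
#'
#' @param vol a [voxel_volume()] or [label_volume()].
#' @param path output path ending in `.nrrd` or `.mhd`.
#' @param dtype one of `"uint8"`, `"int16"`, `"uint16"`, `"float"`,
#'   `"double"`; default float for grayscale, uint8 for labels.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dtype = NULL) {
  is_label <- inherits(vol, "label_volume")
  arr <- if (is_label) vol$labels else vol$data
  if (is.null(dtype)) dtype <- if (is_label) "uint8" else "float"
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") write_nrrd(arr, vol$spacing, vol$origin, path, dtype)
  else if (ext == "mhd") write_mhd(arr, vol$spacing, vol$origin, path, dtype)
  else stop("write_volume supports .nrrd and .mhd", call. = FALSE)
  invisible(path)
}

dtype_info <- function(dtype) {
  switch(dtype,
    uint8 = list(what = "integer", size = 1L, signed = FALSE,
                 nrrd = "uint8", mhd = "MET_UCHAR"),
    int16 = list(what = "integer", size = 2L, signed = TRUE,
                 nrrd = "int16", mhd = "MET_SHORT"),
    uint16 = list(what = "integer", size = 2L, signed = FALSE,
                  nrrd = "uint16", mhd = "MET_USHORT"),
    int32 = list(what = "integer", size = 4L, signed = TRUE,
                 nrrd = "int32", mhd = "MET_INT"),
    float = list(what = "numeric", size = 4L, signed = TRUE,
                 nrrd = "float", mhd = "MET_FLOAT"),
    double = list(what = "numeric", size = 8L, signed = TRUE,
                  nrrd = "double", mhd = "MET_DOUBLE"),
    stop(sprintf("unsupported dtype: %s", dtype), call. = FALSE)
  )
}

nrrd_type_map <- c(
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
  "uint8_t" = "uint8", "short" = "int16", "int16" = "int16",
  "int16_t" = "int16", "ushort" = "uint16", "uint16" = "uint16",
  "uint16_t" = "uint16", "int" = "int32", "int32" = "int32",
  "int32_t" = "int32", "float" = "float", "double" = "double"
)

write_nrrd <- function(arr, spacing, origin, path, dtype) {
  info <- dtype_info(dtype)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", info$nrrd),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("spacings: %.9g %.9g %.9g", spacing[1], spacing[2], spacing[3]),
    sprintf("axis mins: %.9g %.9g %.9g", origin[1], origin[2], origin[3]),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  vals <- if (info$what == "integer") as.integer(round(arr)) else as.numeric(arr)
  writeBin(vals, con, size = info$size, endian = "little")
}

parse_kv_header <- function(lines, sep) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexpr(sep, ln))
    if (length(m) == 0L) next
    pos <- regexpr(sep, ln)
    key <- trimws(substr(ln, 1, pos - 1))
    val <- trimws(substr(ln, pos + attr(pos, "match.length"), nchar(ln)))
    kv[[tolower(key)]] <- val
  }
  kv
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file", call. = FALSE)
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    hdr <- c(hdr, ln)
  }
  kv <- parse_kv_header(hdr[!grepl("^#", hdr)], ": ")
  if (is.null(kv$encoding) || tolower(kv$encoding) != "raw")
    stop("only raw NRRD encoding is supported", call. = FALSE)
  type <- nrrd_type_map[[tolower(kv$type)]]
  if (is.null(type)) stop(sprintf("unsupported NRRD type: %s", kv$type), call. = FALSE)
  info <- dtype_info(type)
  sizes <- as.integer(strsplit(kv$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD volumes are supported", call. = FALSE)
  n <- prod(sizes)
  endian <- if (!is.null(kv$endian)) tolower(kv$endian) else "little"
  vals <- readBin(con, what = info$what, n = n, size = info$size,
                  signed = info$signed || info$size > 2, endian = endian)
  if (length(vals) < n) stop("truncated NRRD data block", call. = FALSE)
  spacing <- if (!is.null(kv$spacings))
    as.numeric(strsplit(kv$spacings, "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.null(kv[["axis mins"]]))
    as.numeric(strsplit(kv[["axis mins"]], "\\s+")[[1]]) else c(0, 0, 0)
  voxel_volume(array(vals, sizes), spacing, origin)
}

write_mhd <- function(arr, spacing, origin, path, dtype) {
  info <- dtype_info(dtype)
  rawfile <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", spacing[1], spacing[2], spacing[3]),
    sprintf("Offset = %.9g %.9g %.9g", origin[1], origin[2], origin[3]),
    sprintf("ElementType = %s", info$mhd),
    sprintf("ElementDataFile = %s", basename(rawfile))
  )
  writeLines(hdr, path)
  con <- file(rawfile, "wb")
  on.exit(close(con))
  vals <- if (info$what == "integer") as.integer(round(arr)) else as.numeric(arr)
  writeBin(vals, con, size = info$size, endian = "little")
}

read_mhd <- function(path) {
  kv <- parse_kv_header(readLines(path), " = ")
  mhd_map <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
               MET_INT = "int32", MET_FLOAT = "float", MET_DOUBLE = "double")
  type <- mhd_map[[kv$elementtype]]
  if (is.null(type)) stop(sprintf("unsupported MHD type: %s", kv$elementtype), call. = FALSE)
  info <- dtype_info(type)
  sizes <- as.integer(strsplit(kv$dimsize, "\\s+")[[1]])
  rawfile <- file.path(dirname(path), kv$elementdatafile)
  con <- file(rawfile, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = info$what, n = prod(sizes), size = info$size,
                  signed = info$signed || info$size > 2, endian = "little")
  if (length(vals) < prod(sizes)) stop("truncated MHD raw file", call. = FALSE)
  spacing <- if (!is.null(kv$elementspacing))
    as.numeric(strsplit(kv$elementspacing, "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.null(kv$offset))
    as.numeric(strsplit(kv$offset, "\\s+")[[1]]) else c(0, 0, 0)
  voxel_volume(array(vals, sizes), spacing, origin)
}

#' Resample a volume to isotropic voxels
#'
#' Downstream geometry (spherical neighbourhoods, local thickness) assumes
#' isotropic spacing, so this is applied once, up front. The target
#' spacing is the smallest input spacing; interpolation is trilinear
#' (nearest-neighbour for label volumes). Already-isotropic volumes are
#' returned unchanged.
#'
#' @param vol a [voxel_volume()] or [label_volume()].
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(vol) {
  if (diff(range(vol$spacing)) <= 1e-9 * mean(vol$spacing)) return(vol)
  target <- min(vol$spacing)
  is_label <- inherits(vol, "label_volume")
  arr <- if (is_label) vol$labels else vol$data
  d <- dim(arr)
  # centre-to-centre extent preserved: sample at multiples of `target`
  outdim <- as.integer(floor((d - 1) * vol$spacing / target + 1e-9) + 1)
  A <- diag(target / vol$spacing)
  res <- cpp_resample_affine(as.numeric(arr), d, A, c(0, 0, 0), outdim,
                             nearest = is_label, fill = 0)
  res <- array(res, outdim)
  if (is_label) label_volume(res, target, vol$origin)
  else voxel_volume(res, target, vol$origin)
}

#' Export an anisotropy vector field
#'
#' CSV columns are `x_um, y_um, z_um, da, ax, ay, az, n_normals`, one row
#' per defined sample; VTK legacy ASCII POLYDATA carries the sample
#' positions as POINTS plus a scalar array `da` and a vector array `axis`
#' (unit norm).
#'
#' @param field an `anisotropy_field` from [map_anisotropy()].
#' @param path output file.
#' @param format `"csv"` or `"vtk-legacy"`.
#' @return `path`, invisibly.
#' @export
export_vector_field <- function(field, path, format = c("csv", "vtk-legacy")) {
  format <- match.arg(format)
  s <- field$samples
  if (nrow(s) == 0L) stop("empty anisotropy field", call. = FALSE)
  if (format == "csv") {
    out <- data.frame(
      x_um = s$x, y_um = s$y, z_um = s$z, da = s$da,
      ax = s$ax, ay = s$ay, az = s$az, n_normals = s$n_normals
    )
    write.csv(out, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    n <- nrow(s)
    writeLines(c("# vtk DataFile Version 3.0",
                 "osteofabric anisotropy vector field",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", n)), con)
    writeLines(sprintf("%.6g %.6g %.6g", s$x, s$y, s$z), con)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "SCALARS da float 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.6g", s$da), con)
    writeLines("VECTORS axis float", con)
    writeLines(sprintf("%g %g %g", s$ax, s$ay, s$az), con)
  }
  invisible(path)
}

#' Export a degree-of-anisotropy histogram
#'
#' Writes `bin_left, bin_right, count` rows. Undefined (sentinel-zero)
#' samples were already discarded when the histogram was built, so counts
#' sum to the number of defined samples.
#'
#' @param hist a `da_histogram` from [da_histogram()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
export_histogram <- function(hist, path) {
  df <- data.frame(bin_left = hist$breaks[-length(hist$breaks)],
                   bin_right = hist$breaks[-1],
                   count = hist$counts)
  df <- df[df$count > 0 | hist$n_defined > 0, ]
  if (hist$n_defined == 0L) df <- df[0, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
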