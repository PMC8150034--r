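#' Filter-chain configuration
#'
#' Defaults reproduce the conditioning chain used ahead of segmentation:
#' a median filter of kernel 3, an edge-preserving (intensity mean-shift)
#' smoother of window 5, third-degree polynomial bias flattening, and an
#' unnormalized difference-of-Gaussians band-pass with sigmas at the
#' midpoints of the 0.5--1.0 and 2.0--4.0 voxel ranges. All filters
#' compute in double precision regardless of the input dtype.
#'
#' @param median_kernel odd integer, voxels.
#' @param smooth_window odd integer, voxels.
#' @param poly_degree polynomial degree for bias correction.
#' @param dog_sigma1,dog_sigma2 Gaussian sigmas in voxels, `sigma2 > sigma1`.
#' @param dog_normalized normalize each Gaussian kernel to unit sum?
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method = "fixed"`.
#' @return a `filter_chain_config` list.
#' @export
filter_chain_config <- function(median_kernel = 3L, smooth_window = 5L,
                                poly_degree = 3L, dog_sigma1 = 0.75,
                                dog_sigma2 = 3.0, dog_normalized = FALSE,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (median_kernel %% 2L == 0L || median_kernel < 1L)
    stop("median_kernel must be odd and >= 1", call. = FALSE)
  if (smooth_window %% 2L == 0L || smooth_window < 3L)
    stop("smooth_window must be odd and >= 3", call. = FALSE)
  if (!(dog_sigma2 > dog_sigma1 && dog_sigma1 > 0))
    stop("need dog_sigma2 > dog_sigma1 > 0", call. = FALSE)
  if (poly_degree < 0) stop("poly_degree must be >= 0", call. = FALSE)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required for threshold_method = 'fixed'", call. = FALSE)
  structure(list(
    median_kernel = as.integer(median_kernel),
    smooth_window = as.integer(smooth_window),
    poly_degree = as.integer(poly_degree),
    dog_sigma1 = dog_sigma1, dog_sigma2 = dog_sigma2,
    dog_normalized = isTRUE(dog_normalized),
    threshold_method = threshold_method,
    fixed_threshold = fixed_threshold
  ), class = "filter_chain_config")
}

with_data <- function(vol, data) {
  voxel_volume(array(data, dim(vol$data)), vol$spacing, vol$origin)
}

#' Median filter
#'
#' Each voxel is replaced by the median of its cubic `kernel^3`
#' neighbourhood; edges are handled by reflection.
#'
#' @param vol a [voxel_volume()].
#' @param kernel odd integer edge length, voxels.
#' @return filtered [voxel_volume()].
#' @export
median_filter <- function(vol, kernel = 3L) {
  if (kernel %% 2L == 0L || kernel < 1L)
    stop("median kernel must be odd and >= 1", call. = FALSE)
  with_data(vol, cpp_median3d(as.numeric(vol$data), dim(vol$data), kernel))
}

#' Edge-preserving mean-shift smoothing
#'
#' Intensity-domain mean shift: each voxel's value iteratively moves to
#' the mean of neighbourhood intensities lying within a range bandwidth
#' of the current value, which smooths within regions while leaving
#' well-separated step edges in place. The default bandwidth is half the
#' Otsu inter-class gap of the volume (the distance between the two class
#' means found by Otsu's criterion). Iteration stops when the shift falls
#' below 1e-3 of the intensity range or after 10 iterations.
#'
#' @param vol a [voxel_volume()].
#' @param window odd spatial window, voxels.
#' @param bandwidth intensity range bandwidth; `NULL` for the Otsu default.
#' @return smoothed [voxel_volume()].
#' @export
edge_preserving_smooth <- function(vol, window = 5L, bandwidth = NULL) {
  if (window %% 2L == 0L || window < 3L)
    stop("smoothing window must be odd and >= 3", call. = FALSE)
  rng <- diff(range(vol$data))
  if (rng == 0) return(vol)
  if (is.null(bandwidth)) {
    ot <- otsu_threshold(vol$data)
    bandwidth <- (ot$mean_high - ot$mean_low) / 2
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- rng / 4
  }
  with_data(vol, cpp_meanshift3d(as.numeric(vol$data), dim(vol$data), window,
                                 bandwidth, 10L, 1e-3 * rng))
}

#' Polynomial bias-field correction
#'
#' Fits a degree-`degree` 3D polynomial in world coordinates to the
#' intensities by least squares and subtracts it, adding back the fitted
#' field's mean so the global mean is preserved. Flattens slowly varying
#' beam-hardening-like shading without touching fine structure.
#'
#' @param vol a [voxel_volume()].
#' @param degree total polynomial degree (default 3).
#' @param max_fit_voxels cap on voxels entering the least-squares fit
#'   (a deterministic stride subsample is used above it).
#' @return corrected [voxel_volume()].
#' @export
polynomial_bias_correct <- function(vol, degree = 3L, max_fit_voxels = 80000L) {
  d <- dim(vol$data)
  expo <- poly_exponents(degree)
  if (prod(d) <= nrow(expo))
    stop("volume too small for the requested polynomial degree", call. = FALSE)
  # normalized coordinates in [-1, 1] for conditioning
  cx <- norm_coord(d[1]); cy <- norm_coord(d[2]); cz <- norm_coord(d[3])
  idx <- seq_len(prod(d))
  if (length(idx) > max_fit_voxels) {
    stride <- ceiling(length(idx) / max_fit_voxels)
    idx <- seq(1L, length(idx), by = stride)
  }
  sub <- arrayInd(idx, d)
  Xfit <- poly_design(cx[sub[, 1]], cy[sub[, 2]], cz[sub[, 3]], expo)
  fit <- lm.fit(Xfit, as.numeric(vol$data)[idx])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # evaluate the fitted field on the full grid, separably per monomial
  field <- array(0, d)
  for (m in seq_len(nrow(expo))) {
    if (beta[m] == 0) next
    term <- outer(outer(cx^expo[m, 1], cy^expo[m, 2]), cz^expo[m, 3])
    field <- field + beta[m] * term
  }
  with_data(vol, vol$data - field + mean(field))
}

norm_coord <- function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n)

poly_exponents <- function(degree) {
  g <- expand.grid(a = 0:degree, b = 0:degree, c = 0:degree)
  as.matrix(g[rowSums(g) <= degree, , drop = FALSE])
}

poly_design <- function(x, y, z, expo) {
  X <- matrix(0, length(x), nrow(expo))
  for (m in seq_len(nrow(expo)))
    X[, m] <- x^expo[m, 1] * y^expo[m, 2] * z^expo[m, 3]
  X
}

#' Difference-of-Gaussians band-pass filter
#'
#' Gaussian(`sigma1`) minus Gaussian(`sigma2`) of the input, sigmas in
#' voxel units. When `normalized` each 1-D Gaussian kernel is scaled to
#' unit sum before subtraction; the default leaves the raw
#' `exp(-i^2 / 2 sigma^2)` weights, matching the unnormalized variant
#' used for trabecular enhancement.
#'
#' @param vol a [voxel_volume()].
#' @param sigma1,sigma2 Gaussian sigmas, voxels; `sigma2 > sigma1 > 0`.
#' @param normalized logical, default `FALSE`.
#' @return filtered [voxel_volume()].
#' @export
dog_filter <- function(vol, sigma1 = 0.75, sigma2 = 3.0, normalized = FALSE) {
  if (!(sigma2 > sigma1 && sigma1 > 0))
    stop("need sigma2 > sigma1 > 0", call. = FALSE)
  v <- as.numeric(vol$data)
  g1 <- cpp_gauss3d(v, dim(vol$data), sigma1, normalized)
  g2 <- cpp_gauss3d(v, dim(vol$data), sigma2, normalized)
  with_data(vol, g1 - g2)
}

# Exhaustive Otsu on a 256-bin histogram of the full intensity range.
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("constant volume has no Otsu threshold", call. = FALSE)
  nb <- 256L
  bin <- pmin(nb - 1L, as.integer((x - lo) / (hi - lo) * nb))
  h <- tabulate(bin + 1L, nbins = nb)
  p <- h / sum(h)
  centres <- lo + (seq_len(nb) - 0.5) / nb * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * centres)
  mu_t <- mu[nb]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-nb])
  thr <- lo + k / nb * (hi - lo)   # boundary between bins k-1 and k (0-based)
  list(threshold = thr,
       mean_low = mu[k] / w0[k],
       mean_high = (mu_t - mu[k]) / max(w1[k], .Machine$double.eps))
}

#' Threshold bone-candidate voxels
#'
#' Otsu's method maximizes the between-class variance over a 256-bin
#' histogram of the full intensity range; `fixed` applies a supplied
#' cutoff. Foreground is `intensity >= threshold` for fixed thresholds
#' and `intensity > threshold` for Otsu (the threshold sits on a bin
#' boundary).
#'
#' @param vol a [voxel_volume()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed intensity cutoff, required for `method = "fixed"`.
#' @return logical 3D array, `TRUE` = bone candidate.
#' @export
threshold_bone <- function(vol, method = c("otsu", "fixed"), fixed = NULL) {
  method <- match.arg(method)
  if (length(vol$data) == 0L) stop("empty volume", call. = FALSE)
  if (method == "fixed") {
    if (is.null(fixed)) stop("`fixed` threshold required", call. = FALSE)
    return(array(vol$data >= fixed, dim(vol$data)))
  }
  thr <- otsu_threshold(vol$data)$threshold
  array(vol$data > thr, dim(vol$data))
}

#' Run the full preprocessing chain
#'
#' Median filter, mean-shift smoothing, polynomial bias correction, and
#' the DoG band-pass, per a [filter_chain_config()]. Returns all
#' intermediate products: the median/mean-shift-smoothed volume (used for
#' the cortical ROI), the bias-corrected volume, the DoG response (used
#' for the trabecular ROI), and the bone-candidate mask from the
#' configured threshold applied to the smoothed volume.
#'
#' @param vol a [voxel_volume()].
#' @param config a [filter_chain_config()].
#' @return list with elements `smoothed`, `flattened`, `dog`, `bone_mask`,
#'   and `config`.
#' @export
preprocess_volume <- function(vol, config = filter_chain_config()) {
  sm <- median_filter(vol, config$median_kernel)
  sm <- edge_preserving_smooth(sm, config$smooth_window)
  fl <- polynomial_bias_correct(sm, config$poly_degree)
  dg <- dog_filter(fl, config$dog_sigma1, config$dog_sigma2,
                   config$dog_normalized)
  mask <- threshold_bone(fl, config$threshold_method,
                         fixed = config$fixed_threshold)
  list(smoothed = sm, flattened = fl, dog = dg, bone_mask = mask,
       config = config)
}
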