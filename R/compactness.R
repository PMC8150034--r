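#' Binarize a midshaft slice
#'
#' Thresholds a grayscale midshaft image (Otsu by default), keeps the
#' largest connected component, and leaves interior holes open — the
#' medullary cavity and inter-trabecular space must stay background for
#' the compactness profile.
#'
#' @param gray_slice 2D numeric matrix (or logical, returned as-is after
#'   the largest-component rule).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed threshold for `method = "fixed"`.
#' @return logical matrix, `TRUE` = bone.
#' @export
binarize_midshaft <- function(gray_slice, method = c("otsu", "fixed"),
                              fixed = NULL) {
  method <- match.arg(method)
  if (is.logical(gray_slice) || all(gray_slice %in% c(0, 1))) {
    bw <- gray_slice > 0.5
  } else if (method == "fixed") {
    if (is.null(fixed)) stop("`fixed` threshold required", call. = FALSE)
    bw <- gray_slice >= fixed
  } else {
    bw <- gray_slice > otsu_threshold(gray_slice)$threshold
  }
  if (!any(bw)) stop("empty foreground after thresholding", call. = FALSE)
  d <- c(dim(bw), 1L)
  cc <- array(cpp_label3d(as.logical(array(bw, d)), d, 26L), d)[, , 1]
  keep <- which.max(tabulate(cc[cc > 0]))
  matrix(cc == keep, nrow(bw), ncol(bw))
}

#' Section, medullary, and ontogenetic centres
#'
#' The section centre is the centroid of the filled periosteal region;
#' the medullary centre is the centroid of interior non-bone pixels
#' (falling back to the section centre when the section is solid); the
#' ontogenetic centre is the interior point minimizing the total residual
#' sum of squares of per-sector sigmoid fits, found by 1-pixel
#' coordinate descent from the section centre.
#'
#' @param section logical matrix from [binarize_midshaft()].
#' @param spacing in-plane pixel spacing, µm.
#' @param n_sectors sectors used for the ontogenetic-centre objective
#'   (coarser than the reporting profile for speed).
#' @param max_moves cap on coordinate-descent moves.
#' @return a `section_centres` list with the three centres (pixel
#'   coordinates, 1-based) and their world equivalents in mm.
#' @export
compute_centres <- function(section, spacing = 1, n_sectors = 12L,
                            max_moves = 30L) {
  if (!any(section)) stop("empty section", call. = FALSE)
  filled <- fill_holes_slicewise(array(section, c(dim(section), 1L)))[, , 1]
  idx <- which(filled)
  co <- arrayInd(idx, dim(section))
  sc <- colMeans(co)
  interior <- filled & !section
  mc <- if (any(interior)) colMeans(arrayInd(which(interior), dim(section))) else sc
  obj <- function(cen) {
    pr <- radial_profile(section, cen, n_sectors = n_sectors,
                         n_radial_bins = 25L)
    sum(vapply(seq_len(n_sectors), function(s) {
      cells <- pr$profile[s, ]
      ok <- !is.na(cells)
      if (sum(ok) < 8L) return(0)
      fit_sigmoid_1d(pr$radial_mid[ok], cells[ok], quick = TRUE)$rss
    }, numeric(1)))
  }
  cen <- round(sc)
  best <- obj(cen)
  moves <- 0L
  repeat {
    improved <- FALSE
    for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      cand <- cen + step
      if (cand[1] < 1 || cand[2] < 1 || cand[1] > nrow(section) ||
          cand[2] > ncol(section)) next
      if (!filled[cand[1], cand[2]]) next
      val <- obj(cand)
      if (val < best - 1e-12) {
        best <- val; cen <- cand; improved <- TRUE
      }
    }
    moves <- moves + 1L
    if (!improved || moves >= max_moves) break
  }
  px_mm <- spacing / 1000
  structure(list(
    section_centre = sc, medullary_centre = mc, ontogenetic_centre = cen,
    section_centre_mm = (sc - 1) * px_mm,
    medullary_centre_mm = (mc - 1) * px_mm,
    ontogenetic_centre_mm = (cen - 1) * px_mm,
    rss = best
  ), class = "section_centres")
}

#' Radial compactness profile
#'
#' Pixels are assigned to angular sectors about the centre and to radial
#' bins by distance normalized per sector to that sector's maximum
#' bone-pixel distance (so radial coordinate 1 is the periosteal boundary
#' in every direction). Compactness is the occupied (bone) fraction per
#' cell; cells with no pixels are `NA` and excluded from fits.
#'
#' @param section logical matrix, `TRUE` = bone.
#' @param centre length-2 centre (pixel coordinates).
#' @param n_sectors number of angular sectors (default 60).
#' @param n_radial_bins number of radial bins (default 51).
#' @return a `compactness_profile` list: `profile` (sectors x bins matrix
#'   of occupied fractions), `counts` (pixels per cell), `radial_mid`
#'   (bin midpoints), `sector_mid` (radians), `centre`.
#' @export
radial_profile <- function(section, centre, n_sectors = 60L,
                           n_radial_bins = 51L) {
  d <- dim(section)
  if (centre[1] < 1 || centre[2] < 1 || centre[1] > d[1] || centre[2] > d[2])
    stop("centre outside the image", call. = FALSE)
  idx <- which(section | !section)  # all pixels
  co <- arrayInd(idx, d)
  dx <- co[, 1] - centre[1]
  dy <- co[, 2] - centre[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  sec <- pmin(n_sectors, as.integer(ang / (2 * pi) * n_sectors) + 1L)
  bone <- as.vector(section)
  rmax <- vapply(seq_len(n_sectors), function(s) {
    rs <- r[sec == s & bone]
    if (length(rs) == 0L) NA_real_ else max(rs)
  }, numeric(1))
  profile <- matrix(NA_real_, n_sectors, n_radial_bins)
  counts <- matrix(0L, n_sectors, n_radial_bins)
  for (s in seq_len(n_sectors)) {
    if (is.na(rmax[s]) || rmax[s] == 0) next
    in_s <- sec == s & r <= rmax[s] + 1e-9
    rn <- r[in_s] / rmax[s]
    bin <- pmin(n_radial_bins, as.integer(rn * n_radial_bins) + 1L)
    tot <- tabulate(bin, nbins = n_radial_bins)
    occ <- tabulate(bin[bone[in_s]], nbins = n_radial_bins)
    counts[s, ] <- tot
    profile[s, tot > 0] <- occ[tot > 0] / tot[tot > 0]
  }
  structure(list(profile = profile, counts = counts,
                 radial_mid = (seq_len(n_radial_bins) - 0.5) / n_radial_bins,
                 sector_mid = (seq_len(n_sectors) - 0.5) * 2 * pi / n_sectors,
                 centre = centre, n_sectors = n_sectors,
                 n_radial_bins = n_radial_bins),
            class = "compactness_profile")
}

# Single sigmoid fit on (d, c) data.  Model:
#   C(d) = Min + (Max - Min) / (1 + exp((P - d) / S))
# The slope at P is (Max - Min) / (4 S): S is the reciprocal-slope
# spread.  Multi-start bounded Levenberg-Marquardt via minpack.lm; the
# quick variant (used inside centre optimization) runs a single
# Nelder-Mead start from the data-driven heuristic.
fit_sigmoid_1d <- function(d, c, quick = FALSE) {
  stopifnot(length(d) == length(c))
  rng <- range(c)
  if (diff(rng) < 0.05) {
    m <- mean(c)
    return(list(min = m, max = m, p = 0.5, s = 0.1,
                rss = sum((c - m)^2), degenerate = TRUE))
  }
  lo_c <- mean(c[d <= quantile(d, 0.2)])
  hi_c <- mean(c[d >= quantile(d, 0.8)])
  mid <- (lo_c + hi_c) / 2
  p0 <- d[which.min(abs(c - mid))]
  starts <- list(c(lo_c, hi_c, p0, 0.05))
  if (!quick) {
    starts <- c(starts, list(
      c(rng[1], rng[2], 0.3, 0.05), c(rng[1], rng[2], 0.5, 0.1),
      c(rng[1], rng[2], 0.7, 0.05), c(rng[1], rng[2], 0.5, 0.02)
    ))
  }
  lower <- c(0, 0, 0, 1e-3)
  upper <- c(1, 1, 1, 2)
  sig <- function(par, d) par[1] + (par[2] - par[1]) /
    (1 + exp((par[3] - d) / par[4]))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- if (quick) {
      res <- optim(st, function(p) sum((c - sig(p, d))^2), method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 60))
      list(par = res$par, rss = res$value, ok = TRUE)
    } else {
      tryCatch({
        nf <- minpack.lm::nls.lm(
          par = st, lower = lower, upper = upper,
          fn = function(p) c - sig(p, d),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
        list(par = coef(nf), rss = sum(residuals(nf)^2), ok = TRUE)
      }, error = function(e) list(ok = FALSE))
    }
    if (isTRUE(fit$ok) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from all starts", call. = FALSE)
  par <- best$par
  if (par[1] > par[2]) par[c(1, 2)] <- par[c(2, 1)]
  list(min = par[1], max = par[2], p = par[3], s = par[4],
       rss = best$rss, degenerate = FALSE)
}

#' Fit the compactness sigmoid
#'
#' Least-squares fit of `C(d) = Min + (Max - Min)/(1 + exp((P - d)/S))`
#' to a [radial_profile()]. `scope = "global"` pools all defined cells;
#' `scope = "per-sector"` fits each sector separately and reports the
#' across-sector mean and SD of each parameter (the angular analysis
#' variables Rmin, Rmax, P ang, S ang) along with the per-sector table.
#' The optimizer is bounded Levenberg--Marquardt with 5 fixed starts;
#' the best residual sum of squares wins.
#'
#' @param profile a [radial_profile()].
#' @param scope `"global"` or `"per-sector"`.
#' @return a `sigmoid_fit` list. Global scope: `min`, `max`, `p`, `s`,
#'   `rss`, `degenerate`. Per-sector scope adds `mean`, `sd`, `median`,
#'   and `per_sector` (one row per fitted sector).
#' @export
fit_sigmoid <- function(profile, scope = c("global", "per-sector")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    dmat <- matrix(profile$radial_mid, profile$n_sectors,
                   profile$n_radial_bins, byrow = TRUE)
    ok <- !is.na(profile$profile)
    if (sum(ok) < 8L) stop("fewer than 8 defined cells", call. = FALSE)
    out <- fit_sigmoid_1d(dmat[ok], profile$profile[ok])
    out$scope <- "global"
    class(out) <- "sigmoid_fit"
    return(out)
  }
  rows <- lapply(seq_len(profile$n_sectors), function(s) {
    cells <- profile$profile[s, ]
    ok <- !is.na(cells)
    if (sum(ok) < 8L) return(NULL)
    f <- fit_sigmoid_1d(profile$radial_mid[ok], cells[ok])
    data.frame(sector = s, min = f$min, max = f$max, p = f$p, s = f$s,
               rss = f$rss, degenerate = f$degenerate)
  })
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per) || nrow(per) == 0L)
    stop("no sector had enough defined cells", call. = FALSE)
  pars <- c("min", "max", "p", "s")
  structure(list(
    scope = "per-sector",
    mean = vapply(per[pars], mean, numeric(1)),
    sd = vapply(per[pars], sd, numeric(1)),
    median = vapply(per[pars], median, numeric(1)),
    rss = sum(per$rss),
    per_sector = per
  ), class = "sigmoid_fit")
}

#' Global observed compactness
#'
#' Bone pixels over all pixels inside the periosteal boundary (the filled
#' section); exactly rotation-invariant under 90-degree rotations.
#'
#' @param section logical matrix, `TRUE` = bone.
#' @return compactness in `[0, 1]`.
#' @export
observed_compactness <- function(section) {
  if (!any(section)) stop("empty section", call. = FALSE)
  filled <- fill_holes_slicewise(array(section, c(dim(section), 1L)))[, , 1]
  sum(section) / sum(filled)
}

#' Classify lifestyle from compactness variables
#'
#' Linear discriminant `score = intercept + sum(coef * variable)`; a
#' positive score calls terrestrial, zero or negative calls aquatic (the
#' boundary is resolved conservatively toward aquatic). The default
#' variable set is `Rmin` alone, the variable that dominates the
#' aquatic--terrestrial axis; published coefficient sets can be supplied
#' via `coefficients`, or refit on labelled data with
#' [fit_lifestyle_coefficients()].
#'
#' @param variables named list/vector of predictor values (e.g.
#'   `c(Rmin = 0.4)`).
#' @param coefficients a `lifestyle_coefficients` object or list with
#'   `intercept`, `coef` (named), and `id`.
#' @return a `lifestyle_call` list with `score`, `call`,
#'   `coefficients_id`.
#' @export
classify_lifestyle <- function(variables, coefficients) {
  need <- names(coefficients$coef)
  miss <- setdiff(need, names(variables))
  if (length(miss))
    stop(sprintf("missing required variable(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  v <- unlist(variables)[need]
  score <- coefficients$intercept + sum(coefficients$coef * v)
  structure(list(score = score,
                 call = if (score > 0) "terrestrial" else "aquatic",
                 coefficients_id = coefficients$id %||% "unnamed"),
            class = "lifestyle_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit lifestyle discriminant coefficients
#'
#' Trains a logistic discriminant (binomial GLM) on a labelled table of
#' compactness variables; the returned linear predictor is oriented so
#' that positive scores mean terrestrial.
#'
#' @param data data.frame containing the predictor columns and a
#'   `lifestyle` column with values `"aquatic"` / `"terrestrial"`.
#' @param predictors character vector of predictor column names
#'   (default `"Rmin"`).
#' @param id provenance tag stored with the coefficients.
#' @return a `lifestyle_coefficients` list.
#' @export
fit_lifestyle_coefficients <- function(data, predictors = "Rmin",
                                       id = "refit") {
  y <- as.integer(data$lifestyle == "terrestrial")
  if (length(unique(y)) < 2L)
    stop("need both lifestyle classes to refit", call. = FALSE)
  f <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(glm(f, data = cbind(data, y = y),
                              family = stats::binomial()))
  cf <- coef(fit)
  structure(list(intercept = unname(cf[1]),
                 coef = cf[-1][predictors], id = id),
            class = "lifestyle_coefficients")
}

#' Full midshaft compactness analysis
#'
#' Binarization, centres, radial profile about the ontogenetic centre,
#' global and per-sector sigmoid fits, observed compactness, and (when
#' coefficients are supplied) the lifestyle call.
#'
#' @param slice 2D grayscale or binary midshaft image.
#' @param spacing in-plane spacing, µm.
#' @param n_sectors,n_radial_bins profile resolution.
#' @param coefficients optional `lifestyle_coefficients`.
#' @return a `compactness_analysis` list.
#' @export
analyse_midshaft <- function(slice, spacing = 1, n_sectors = 60L,
                             n_radial_bins = 51L, coefficients = NULL) {
  section <- binarize_midshaft(slice)
  centres <- compute_centres(section, spacing)
  profile <- radial_profile(section, centres$ontogenetic_centre,
                            n_sectors, n_radial_bins)
  global <- fit_sigmoid(profile, "global")
  angular <- fit_sigmoid(profile, "per-sector")
  cg <- observed_compactness(section)
  call <- NULL
  if (!is.null(coefficients)) {
    call <- classify_lifestyle(c(Rmin = unname(angular$mean["min"])),
                               coefficients)
  }
  structure(list(section = section, centres = centres, profile = profile,
                 global = global, angular = angular, cg = cg,
                 lifestyle = call),
            class = "compactness_analysis")
}
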