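#' Cross-sectional areas of a labelled slice
#'
#' Areas from voxel counts times spacing squared, reported in mm^2.
#' `Tt.Ar` covers labels 1--3 (everything inside the periosteal
#' boundary), `Ct.Ar` label 1, `Ma.Ar` label 3. The stiffness score `R/t`
#' uses the equivalent-circle radius `sqrt(Tt.Ar / pi)` over the mean
#' cortical thickness of the slice.
#'
#' @param label_slice 2D integer matrix of labels (scheme as in
#'   [label_volume()]).
#' @param spacing in-plane voxel spacing, µm (isotropic).
#' @return list with `tt_ar`, `ct_ar`, `ma_ar`, `tb_ar`, `ct_ar_frac`,
#'   `ct_th_mm`, `r_over_t` (all areas mm^2).
#' @export
section_areas <- function(label_slice, spacing) {
  sp <- spacing[1]
  if (!any(label_slice == 1L | label_slice == 2L))
    stop("slice contains no bone", call. = FALSE)
  px_mm2 <- sp^2 / 1e6
  tt <- sum(label_slice %in% 1:3) * px_mm2
  ct <- sum(label_slice == 1L) * px_mm2
  tb <- sum(label_slice == 2L) * px_mm2
  ma <- sum(label_slice == 3L) * px_mm2
  ct_th <- NA_real_
  r_over_t <- NA_real_
  if (ct > 0) {
    m <- array(label_slice == 1L, c(dim(label_slice), 1L))
    th <- cpp_local_thickness(as.logical(m), dim(m))
    ct_th <- mean(th[as.logical(m)]) * sp / 1000  # mm
    R <- sqrt(tt / pi)
    r_over_t <- R / ct_th
  }
  list(tt_ar = tt, ct_ar = ct, ma_ar = ma, tb_ar = tb,
       ct_ar_frac = if (tt > 0) ct / tt else NA_real_,
       ct_th_mm = ct_th, r_over_t = r_over_t)
}

#' Bone volume fractions
#'
#' `region = "whole"` takes TV over labels 1--3 and BV over bone labels
#' 1--2; `region = "trabecular-compartment"` takes TV over labels 2--3
#' (the endosteal compartment) and BV over label 2. Volumes in mm^3.
#'
#' @param label a [label_volume()].
#' @param region `"whole"` or `"trabecular-compartment"`.
#' @return list with `bv`, `tv` (mm^3) and `bvtv`.
#' @export
volume_fractions <- function(label,
                             region = c("whole", "trabecular-compartment")) {
  region <- match.arg(region)
  sp <- label$spacing
  vox_mm3 <- prod(sp) / 1e9
  lab <- label$labels
  if (region == "whole") {
    tv <- sum(lab > 0L); bv <- sum(lab == 1L | lab == 2L)
  } else {
    tv <- sum(lab == 2L | lab == 3L); bv <- sum(lab == 2L)
  }
  if (tv == 0L) stop(sprintf("region '%s' is empty", region), call. = FALSE)
  list(bv = bv * vox_mm3, tv = tv * vox_mm3, bvtv = bv / tv)
}

#' Local thickness map (largest inscribed sphere)
#'
#' Hildebrand--Rüegsegger local thickness: the thickness at a point is
#' the diameter of the largest sphere that contains the point and fits
#' inside the structure, computed by distance-transform sphere painting.
#' Used for both `Ct.Th` (label 1) and `Tb.Th` (label 2).
#'
#' @param mask logical 3D array.
#' @param spacing isotropic voxel spacing, µm.
#' @return list with `map` (thickness in µm, 0 outside) and `mean_um`.
#' @export
local_thickness <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  sp <- spacing[1]
  th <- cpp_local_thickness(as.logical(mask), dim(mask)) * sp
  th <- array(th, dim(mask))
  list(map = th, mean_um = mean(th[mask]))
}

#' Proximal--distal length
#'
#' Extent of the mask along the slice axis, in mm; invariant to flipping
#' the slice order.
#'
#' @param mask logical 3D array (axis-aligned whole-bone mask).
#' @param spacing voxel spacing, µm.
#' @return length in mm.
#' @export
pd_length <- function(mask, spacing) {
  occ <- which(apply(mask, 3, any))
  if (length(occ) == 0L) stop("empty mask", call. = FALSE)
  sp <- if (length(spacing) == 3L) spacing[3] else spacing[1]
  (max(occ) - min(occ) + 1L) * sp / 1000
}

#' Full morphometry table for one specimen
#'
#' Computes the standard metric set from a segmented, axis-aligned label
#' volume: midshaft cross-section areas, compartment volumes and
#' fractions, cortical and trabecular thickness, and proximal--distal
#' length. "Average" areas are the mean over diaphyseal slices between
#' 25% and 75% of P--D; the midshaft-only values are reported alongside.
#'
#' @param label a [label_volume()] (axis aligned, isotropic).
#' @param midshaft optional `midshaft_selection`; computed when `NULL`.
#' @return one-row data.frame with columns `Tt.Ar`, `Ct.Ar`, `Ma.Ar`,
#'   `Ct.Ar/Tt.Ar`, `Ct.Th`, `Tb.Th`, `BV`, `TV`, `BV/TV`,
#'   `BV/TV.trab`, `P-D`, `R/t` plus midshaft-only area columns.
#' @export
morphometry_table <- function(label, midshaft = NULL) {
  sp <- require_isotropic(label, "morphometry_table")
  if (is.null(midshaft)) midshaft <- find_midshaft(label)
  d <- dim(label$labels)
  whole <- whole_bone_mask(label)
  pd <- pd_length(whole, label$spacing)
  occ <- which(apply(whole, 3, any))
  span <- occ[occ >= quantile(occ, 0.25) & occ <= quantile(occ, 0.75)]
  mids <- section_areas(label$labels[, , midshaft$slice_index], sp)
  avg <- lapply(span, function(k) {
    sl <- label$labels[, , k]
    if (!any(sl == 1L | sl == 2L)) return(NULL)
    section_areas(sl, sp)
  })
  avg <- avg[!vapply(avg, is.null, logical(1))]
  mean_of <- function(f) mean(vapply(avg, `[[`, numeric(1), f), na.rm = TRUE)
  vw <- volume_fractions(label, "whole")
  vt <- tryCatch(volume_fractions(label, "trabecular-compartment"),
                 error = function(e) list(bvtv = NA_real_))
  ct_th <- if (any(label$labels == 1L))
    local_thickness(label$labels == 1L, sp)$mean_um / 1000 else NA_real_
  tb_th <- if (any(label$labels == 2L))
    local_thickness(label$labels == 2L, sp)$mean_um / 1000 else NA_real_
  df <- data.frame(
    Tt.Ar = mean_of("tt_ar"), Ct.Ar = mean_of("ct_ar"),
    Ma.Ar = mean_of("ma_ar"),
    Ct.Th = ct_th, Tb.Th = tb_th,
    BV = vw$bv, TV = vw$tv,
    `P-D` = pd, `R/t` = mids$r_over_t,
    Tt.Ar.mid = mids$tt_ar, Ct.Ar.mid = mids$ct_ar, Ma.Ar.mid = mids$ma_ar,
    midshaft_slice = midshaft$slice_index,
    check.names = FALSE
  )
  df[["Ct.Ar/Tt.Ar"]] <- df$Ct.Ar / df$Tt.Ar
  df[["BV/TV"]] <- vw$bvtv
  df[["BV/TV.trab"]] <- vt$bvtv
  nm <- c("Tt.Ar", "Ct.Ar", "Ma.Ar", "Ct.Ar/Tt.Ar", "Ct.Th", "Tb.Th",
          "BV", "TV", "BV/TV", "BV/TV.trab", "P-D", "R/t",
          "Tt.Ar.mid", "Ct.Ar.mid", "Ma.Ar.mid", "midshaft_slice")
  df[, nm]
}
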