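#' SUVmax and SUVmean over a VOI
#'
#' @param vol A [pet_volume()] in SUV.
#' @param voi A non-empty [voi_mask()] on the same grid.
#' @return List with `suv_max` and `suv_mean` over the full VOI.
#' @export
suv_statistics <- function(vol, voi) {
  stopifnot(inherits(vol, "pet_volume"), inherits(voi, "voi_mask"))
  require_suv(vol)
  check_same_grid(vol, voi)
  if (length(voi) == 0L)
    stop("SUV statistics undefined on empty VOI (", voi$component, ")",
         call. = FALSE)
  vals <- vol$values[voi$indices]
  list(suv_max = max(vals), suv_mean = mean(vals))
}

#' SUVpeak: mean SUV in a 1 cm^3 sphere at the hottest voxel
#'
#' SUVpeak is defined as the mean SUV within a sphere of `sphere_cm3`
#' (default 1.0 cm^3, diameter about 12.4 mm) centered on the VOI's maximum
#' voxel, intersected with the image grid. Sphere membership is decided by
#' voxel-center distance; with multiple equal maxima the one with the lowest
#' linear index is used, so the result is deterministic. The sphere may
#' extend beyond the VOI (but never beyond the grid), as is conventional for
#' a local peak average.
#'
#' @inheritParams suv_statistics
#' @param sphere_cm3 Sphere volume in cm^3.
#' @return SUVpeak value; always <= SUVmax.
#' @export
suv_peak <- function(vol, voi, sphere_cm3 = 1.0) {
  stopifnot(inherits(vol, "pet_volume"), inherits(voi, "voi_mask"))
  require_suv(vol)
  check_same_grid(vol, voi)
  if (length(voi) == 0L)
    stop("SUVpeak undefined on empty VOI (", voi$component, ")", call. = FALSE)
  vals <- vol$values[voi$indices]
  center_lin <- voi$indices[which.max(vals)]  # lowest linear index on ties
  d <- dim(vol$values)
  center <- arrayInd(center_lin, d)
  radius_mm <- (3 * sphere_cm3 * 1000 / (4 * pi))^(1 / 3)  # 1000 mm^3 per cm^3
  sp <- vol$spacing
  # candidate voxel index ranges around the center
  rng <- lapply(1:3, function(a) {
    k <- ceiling(radius_mm / sp[a])
    max(1L, center[a] - k):min(d[a], center[a] + k)
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  dist2 <- ((g$i - center[1]) * sp[1])^2 + ((g$j - center[2]) * sp[2])^2 +
    ((g$k - center[3]) * sp[3])^2
  inside <- dist2 <= radius_mm^2
  lin <- g$i[inside] + d[1] * (g$j[inside] - 1L) +
    d[1] * d[2] * (g$k[inside] - 1L)
  mean(vol$values[lin])
}

#' Lesion-to-background ratio (LBR)
#'
#' SUVmax of the lesion VOI divided by the mean SUV of the blood-pool
#' background region (the descending aorta).
#'
#' @inheritParams suv_statistics
#' @param background A non-empty [voi_mask()] for the background region,
#'   with positive mean SUV.
#' @return Dimensionless ratio.
#' @export
lesion_background_ratio <- function(vol, voi, background) {
  stopifnot(inherits(background, "voi_mask"))
  num <- suv_statistics(vol, voi)$suv_max
  bg <- suv_statistics(vol, background)$suv_mean
  if (bg <= 0)
    stop("background mean SUV must be positive (got ", format(bg), ")",
         call. = FALSE)
  num / bg
}

#' Total metabolic burden over the five device components
#'
#' Sums MTV and TLG across the five LVAD components for one threshold rule.
#' Absent components contribute zero; the background region is excluded.
#'
#' @param seg A data frame as returned by [segment_all()] (or a subset of
#'   its rows) holding at most one row per component, all under one rule.
#' @param mode Which rule's rows to aggregate when `seg` holds both
#'   (`"fixed_absolute"` or `"fixed_relative"`); `NULL` requires `seg` to be
#'   single-rule already.
#' @return List with `total_mtv` (cm^3), `total_tlg`, `mode`.
#' @export
total_burden <- function(seg, mode = NULL) {
  stopifnot(is.data.frame(seg),
            all(c("component", "mode", "mtv_cm3", "tlg") %in% names(seg)))
  if (!is.null(mode)) seg <- seg[seg$mode == mode, , drop = FALSE]
  modes <- unique(seg$mode)
  if (length(modes) != 1L)
    stop("segmentation results mix threshold rules: ",
         paste(modes, collapse = ", "), call. = FALSE)
  seg <- seg[seg$component %in% lvad_components(), , drop = FALSE]
  if (anyDuplicated(seg$component))
    stop("more than one result per component", call. = FALSE)
  list(total_mtv = sum(seg$mtv_cm3), total_tlg = sum(seg$tlg), mode = modes)
}

#' Per-patient lesion metrics across all device components
#'
#' Computes, per device component, SUVmax, SUVmean, SUVpeak, LBR and the
#' segmentation results under both threshold rules, plus a patient-level
#' `total` row. On the total row the SUV-type metrics are the maximum across
#' components (the per-patient summary used for patient-level ROC) and the
#' volumetric columns hold the total MTV / TLG sums.
#'
#' @param vol A [pet_volume()] in SUV.
#' @param vois Named list of [voi_mask()]s including `background_aorta`.
#' @param patient_id Identifier written into every row.
#' @param abs_level,rel_fraction Threshold parameters (defaults SUV 3.0 and
#'   50% of SUVmax).
#' @return Data frame with columns `patient_id`, `component`, `suv_max`,
#'   `suv_mean`, `suv_peak`, `lbr`, `mtv_abs`, `tlg_abs`, `mtv_rel`,
#'   `tlg_rel`. Absent components carry NA SUV metrics and zero volumes.
#' @export
quantify_patient <- function(vol, vois, patient_id = "anonymous",
                             abs_level = 3.0, rel_fraction = 0.5) {
  require_suv(vol)
  bg <- vois[[background_component()]]
  if (is.null(bg) || length(bg) == 0L)
    stop("background_aorta mask is required for LBR", call. = FALSE)
  rules <- list(threshold_rule("fixed_absolute", absolute_level = abs_level),
                threshold_rule("fixed_relative", relative_fraction = rel_fraction))
  seg <- segment_all(vol, vois, rules)
  seg_abs <- seg[seg$mode == "fixed_absolute", ]
  seg_rel <- seg[seg$mode == "fixed_relative", ]
  rows <- lapply(lvad_components(), function(comp) {
    voi <- vois[[comp]]
    a <- seg_abs[seg_abs$component == comp, ]
    r <- seg_rel[seg_rel$component == comp, ]
    if (is.null(voi) || length(voi) == 0L) {
      data.frame(patient_id = patient_id, component = comp,
                 suv_max = NA_real_, suv_mean = NA_real_,
                 suv_peak = NA_real_, lbr = NA_real_,
                 mtv_abs = 0, tlg_abs = 0, mtv_rel = 0, tlg_rel = 0)
    } else {
      s <- suv_statistics(vol, voi)
      data.frame(patient_id = patient_id, component = comp,
                 suv_max = s$suv_max, suv_mean = s$suv_mean,
                 suv_peak = suv_peak(vol, voi),
                 lbr = lesion_background_ratio(vol, voi, bg),
                 mtv_abs = a$mtv_cm3, tlg_abs = a$tlg,
                 mtv_rel = r$mtv_cm3, tlg_rel = r$tlg)
    }
  })
  per_comp <- do.call(rbind, rows)
  tot_abs <- total_burden(seg_abs)
  tot_rel <- total_burden(seg_rel)
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  total <- data.frame(patient_id = patient_id, component = "total",
                      suv_max = safe_max(per_comp$suv_max),
                      suv_mean = safe_max(per_comp$suv_mean),
                      suv_peak = safe_max(per_comp$suv_peak),
                      lbr = safe_max(per_comp$lbr),
                      mtv_abs = tot_abs$total_mtv, tlg_abs = tot_abs$total_tlg,
                      mtv_rel = tot_rel$total_mtv, tlg_rel = tot_rel$total_tlg)
  rbind(per_comp, total)
}
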