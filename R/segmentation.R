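#' Threshold rule for metabolic-volume segmentation
#'
#' Two rules are supported, mirroring clinical practice for metabolic
#' tumor-volume delineation: a fixed absolute SUV cutoff (default SUV 3.0)
#' and a fixed relative cutoff at a fraction of the VOI's SUVmax (default
#' 50%). Both are applied inclusively: a voxel is segmented when its SUV is
#' greater than or equal to the effective threshold.
#'
#' @param mode `"fixed_absolute"` or `"fixed_relative"`.
#' @param absolute_level SUV cutoff for the absolute rule; must be > 0.
#' @param relative_fraction Fraction of SUVmax for the relative rule, in
#'   (0, 1].
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(mode = c("fixed_absolute", "fixed_relative"),
                           absolute_level = 3.0, relative_fraction = 0.5) {
  mode <- match.arg(mode)
  absolute_level <- as.numeric(absolute_level)
  relative_fraction <- as.numeric(relative_fraction)
  if (!is.finite(absolute_level) || absolute_level <= 0)
    stop("absolute_level must be > 0", call. = FALSE)
  if (!is.finite(relative_fraction) || relative_fraction <= 0 ||
      relative_fraction > 1)
    stop("relative_fraction must be in (0, 1]", call. = FALSE)
  structure(list(mode = mode, absolute_level = absolute_level,
                 relative_fraction = relative_fraction),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  if (x$mode == "fixed_absolute")
    cat(sprintf("<threshold_rule> fixed absolute, SUV >= %g\n", x$absolute_level))
  else
    cat(sprintf("<threshold_rule> fixed relative, SUV >= %g%% of SUVmax\n",
                100 * x$relative_fraction))
  invisible(x)
}

#' Effective SUV threshold of a rule within a VOI
#'
#' For the absolute rule this is the configured level; for the relative rule
#' it is `relative_fraction * max(SUV)` over the VOI, so it is always
#' computed per VOI (per device component), never globally.
#'
#' @param vol A [pet_volume()] in SUV.
#' @param voi A non-empty [voi_mask()] on the same grid.
#' @param rule A [threshold_rule()].
#' @return The effective threshold in SUV.
#' @export
effective_threshold <- function(vol, voi, rule) {
  stopifnot(inherits(vol, "pet_volume"), inherits(voi, "voi_mask"),
            inherits(rule, "threshold_rule"))
  require_suv(vol)
  check_same_grid(vol, voi)
  if (rule$mode == "fixed_absolute") return(rule$absolute_level)
  if (length(voi) == 0L)
    stop("relative threshold undefined on empty VOI (", voi$component, ")",
         call. = FALSE)
  rule$relative_fraction * max(vol$values[voi$indices])
}

require_suv <- function(vol) {
  if (vol$unit != "SUV")
    stop("volume must be in SUV units (got ", vol$unit,
         "); run activity_to_suv() first", call. = FALSE)
  invisible(TRUE)
}

seg_result <- function(component, rule, threshold, idx_seg, vol,
                       absent = FALSE) {
  n <- length(idx_seg)
  vv <- voxel_volume(vol)
  mtv <- n * vv
  suv_mean_seg <- if (n > 0L) mean(vol$values[idx_seg]) else 0
  structure(list(component = component, rule = rule,
                 threshold_applied = threshold, n_voxels = n,
                 mtv = mtv, suv_mean_seg = suv_mean_seg,
                 tlg = mtv * suv_mean_seg, absent = absent),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s [%s, t=%s]: %d voxels, MTV %.4g cm^3, TLG %.4g\n",
              x$component, x$rule$mode,
              format(x$threshold_applied), x$n_voxels, x$mtv, x$tlg))
  invisible(x)
}

#' Segment the metabolically active volume within a VOI
#'
#' The segmented set is every VOI voxel whose SUV is greater than or equal
#' to the rule's effective threshold (inclusive). All suprathreshold voxels
#' count, with no connectivity constraint: the VOI itself restricts the
#' region. MTV is the voxel count times the voxel volume (cm^3); TLG is
#' MTV times the mean SUV of the segmented voxels. An empty segmentation is
#' permitted and yields MTV = TLG = 0.
#'
#' @inheritParams effective_threshold
#' @return A `segmentation_result` with fields `component`, `rule`,
#'   `threshold_applied`, `n_voxels`, `mtv` (cm^3), `suv_mean_seg`, `tlg`.
#' @export
segment_voi <- function(vol, voi, rule) {
  stopifnot(inherits(voi, "voi_mask"))
  if (length(voi) == 0L)
    stop("cannot segment an empty VOI (", voi$component,
         "); use segment_all() for cohorts with absent components",
         call. = FALSE)
  thr <- effective_threshold(vol, voi, rule)
  vals <- vol$values[voi$indices]
  seg_result(voi$component, rule, thr, voi$indices[vals >= thr], vol)
}

#' Segment all device components under both threshold rules
#'
#' Runs [segment_voi()] for each of the five device components under each
#' supplied rule. Components whose masks are empty (explicitly absent) yield
#' zero-volume results flagged `absent`.
#'
#' @param vol A [pet_volume()] in SUV.
#' @param vois Named list of [voi_mask()]s as returned by [load_voi_masks()];
#'   only the five device components are used (the background mask, if
#'   present, is ignored here).
#' @param rules List of [threshold_rule()]s (default: fixed absolute 3.0 and
#'   fixed relative 50%).
#' @return A data frame with one row per component x rule: `component`,
#'   `mode`, `threshold_applied`, `n_voxels`, `mtv_cm3`, `suv_mean_seg`,
#'   `tlg`, `absent`.
#' @export
segment_all <- function(vol, vois,
                        rules = list(threshold_rule("fixed_absolute"),
                                     threshold_rule("fixed_relative"))) {
  comps <- lvad_components()
  rows <- list()
  for (rule in rules) {
    for (comp in comps) {
      voi <- vois[[comp]]
      if (is.null(voi) || length(voi) == 0L) {
        thr <- if (rule$mode == "fixed_absolute") rule$absolute_level else NA_real_
        res <- list(component = comp, mode = rule$mode,
                    threshold_applied = thr, n_voxels = 0L, mtv_cm3 = 0,
                    suv_mean_seg = 0, tlg = 0, absent = TRUE)
      } else {
        s <- segment_voi(vol, voi, rule)
        res <- list(component = comp, mode = rule$mode,
                    threshold_applied = s$threshold_applied,
                    n_voxels = s$n_voxels, mtv_cm3 = s$mtv,
                    suv_mean_seg = s$suv_mean_seg, tlg = s$tlg,
                    absent = FALSE)
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}
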