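# Digital LVAD-PET phantoms and simulated lesion-metric cohorts.
#
# World-coordinate convention: all geometry is specified in mm, with the
# origin at the center of the first voxel; the center of voxel (i, j, k)
# (1-based R indices) is ((i-1)*sx, (j-1)*sy, (k-1)*sz).

# Evaluate with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Geometric primitives for phantom components
#'
#' Solids are specified in world mm (see the package vignette for the
#' coordinate convention). `cyl_solid` supports an arbitrary axis
#' direction; membership of a voxel is decided by its center point.
#'
#' @param center Length-3 center, mm.
#' @param radius Radius, mm.
#' @param axis Length-3 axis direction (normalized internally).
#' @param length Full cylinder length, mm.
#' @param extent Length-3 full box widths, mm.
#' @return A primitive description list.
#' @export
sphere_solid <- function(center, radius) {
  list(type = "sphere", center = as.numeric(center), radius = as.numeric(radius))
}

#' @rdname sphere_solid
#' @export
cyl_solid <- function(center, axis, radius, length) {
  u <- as.numeric(axis)
  u <- u / sqrt(sum(u^2))
  list(type = "cylinder", center = as.numeric(center), axis = u,
       radius = as.numeric(radius), length = as.numeric(length))
}

#' @rdname sphere_solid
#' @export
box_solid <- function(center, extent) {
  list(type = "box", center = as.numeric(center), extent = as.numeric(extent))
}

solid_bbox <- function(s) {
  h <- switch(s$type,
    sphere = rep(s$radius, 3),
    box = s$extent / 2,
    cylinder = abs(s$axis) * s$length / 2 +
      s$radius * sqrt(pmax(0, 1 - s$axis^2)))
  rbind(lo = s$center - h, hi = s$center + h)
}

solid_mask <- function(s, X, Y, Z) {
  dx <- X - s$center[1]; dy <- Y - s$center[2]; dz <- Z - s$center[3]
  switch(s$type,
    sphere = dx^2 + dy^2 + dz^2 <= s$radius^2,
    box = abs(dx) <= s$extent[1] / 2 & abs(dy) <= s$extent[2] / 2 &
      abs(dz) <= s$extent[3] / 2,
    cylinder = {
      t <- dx * s$axis[1] + dy * s$axis[2] + dz * s$axis[3]
      r2 <- dx^2 + dy^2 + dz^2 - t^2
      abs(t) <= s$length / 2 & r2 <= s$radius^2
    })
}

#' Default stylized LVAD component geometry
#'
#' A non-anatomical but topologically sensible arrangement on the default
#' 96^3 grid at 2 mm spacing: the pump housing as a wide cylinder, the
#' inflow cannula rising from it, the outflow graft as a long thin tube,
#' the subcutaneous driveline as a thin tube running towards the body
#' surface, the driveline exit site as a small sphere at its end, and a
#' descending-aorta blood-pool tube as the background reference. All six
#' are pairwise disjoint.
#'
#' @param hotspot_suv Named numeric vector of plateau SUVs for the five
#'   device components.
#' @param aorta_suv Blood-pool plateau SUV (default 1.7).
#' @return Named list of `list(solid, suv)` entries, in labelmap order.
#' @export
default_phantom_components <- function(
    hotspot_suv = c(driveline_exit = 6.0, driveline_subcutaneous = 4.5,
                    pump = 5.0, inflow_cannula = 3.5, outflow_graft = 2.5),
    aorta_suv = 1.7) {
  stopifnot(all(lvad_components() %in% names(hotspot_suv)),
            all(hotspot_suv >= 0), aorta_suv >= 0)
  list(
    driveline_exit = list(
      solid = sphere_solid(c(10, 95, 80), radius = 6),
      suv = unname(hotspot_suv["driveline_exit"])),
    driveline_subcutaneous = list(
      solid = cyl_solid(c(45, 95, 80), axis = c(1, 0, 0), radius = 4,
                        length = 50),
      suv = unname(hotspot_suv["driveline_subcutaneous"])),
    pump = list(
      solid = cyl_solid(c(95, 95, 50), axis = c(0, 0, 1), radius = 16,
                        length = 30),
      suv = unname(hotspot_suv["pump"])),
    inflow_cannula = list(
      solid = cyl_solid(c(95, 95, 75), axis = c(0, 0, 1), radius = 6,
                        length = 16),
      suv = unname(hotspot_suv["inflow_cannula"])),
    outflow_graft = list(
      solid = cyl_solid(c(95, 130, 95), axis = c(0, 1, 0), radius = 6,
                        length = 60),
      suv = unname(hotspot_suv["outflow_graft"])),
    background_aorta = list(
      solid = cyl_solid(c(140, 60, 95), axis = c(0, 0, 1), radius = 9,
                        length = 100),
      suv = aorta_suv)
  )
}

#' Phantom specification
#'
#' Describes a digital LVAD-PET phantom: grid, uniform background SUV,
#' component solids with plateau ("hotspot") SUVs, an optional
#' attenuation-artifact rim around the pump, optional additive Gaussian
#' noise and optional isotropic Gaussian smoothing. With no noise and no
#' smoothing every voxel value is exactly the background or a plateau
#' value, which is what makes the emitted ground truth analytic.
#'
#' @param shape Grid dimensions (default `c(96, 96, 96)`).
#' @param spacing Voxel spacing in mm (default 2 mm isotropic).
#' @param background_suv Background plateau SUV (default 1.0).
#' @param components Named list from [default_phantom_components()] (or the
#'   same structure with custom solids/SUVs).
#' @param artifact_rim `NULL`, or `list(width = mm, suv = value)` describing
#'   a plateau ring painted around the pump in otherwise-background voxels,
#'   emulating an attenuation-correction artifact. It is part of the image
#'   only and never part of any component mask.
#' @param noise_sigma SD of additive Gaussian noise in SUV (0 = none).
#' @param smoothing_fwhm FWHM in mm of isotropic Gaussian smoothing
#'   (0 = none).
#' @param seed Integer seed controlling the noise (determinism contract).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         background_suv = 1.0,
                         components = default_phantom_components(),
                         artifact_rim = NULL, noise_sigma = 0,
                         smoothing_fwhm = 0, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0),
            is.finite(background_suv), background_suv >= 0,
            noise_sigma >= 0, smoothing_fwhm >= 0)
  if (!all(all_components() %in% names(components)))
    stop("components must cover the five device components plus background_aorta",
         call. = FALSE)
  world_hi <- (shape - 1L) * spacing
  for (nm in names(components)) {
    bb <- solid_bbox(components[[nm]]$solid)
    if (any(bb["lo", ] < 0) || any(bb["hi", ] > world_hi))
      stop("geometry out of grid for component ", nm, call. = FALSE)
    if (components[[nm]]$suv < 0)
      stop("hotspot SUV must be >= 0 for component ", nm, call. = FALSE)
  }
  if (!is.null(artifact_rim))
    stopifnot(is.list(artifact_rim), artifact_rim$width > 0,
              artifact_rim$suv >= 0)
  structure(list(shape = shape, spacing = spacing,
                 background_suv = background_suv, components = components,
                 artifact_rim = artifact_rim, noise_sigma = noise_sigma,
                 smoothing_fwhm = smoothing_fwhm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing of a 3-D array; truncated kernels are
# renormalized at the edges so plateaus far from boundaries are preserved.
gaussian_smooth_3d <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  d <- dim(arr)
  for (axis in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing[axis]
    half <- max(1L, ceiling(3 * sigma_vox))
    kern <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
    n <- d[axis]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- kern[ok] / sum(kern[ok])
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = n)
    sm <- K %*% m
    arr <- aperm(array(sm, d[perm]), order(perm))
  }
  arr
}

#' Generate a digital LVAD-PET phantom
#'
#' Returns the SUV volume, the integer labelmap with its label table, the
#' per-component masks, and a ground-truth table listing, per component and
#' per threshold rule (fixed absolute 3.0, fixed relative 50%), the exact
#' voxel count, MTV, segmented-mean SUV and TLG implied by the plateau
#' values. The ground truth is analytic and exact only when `noise_sigma`
#' and `smoothing_fwhm` are both zero. Output is deterministic given the
#' spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param abs_level,rel_fraction Threshold parameters the ground-truth table
#'   is computed for (defaults SUV 3.0 and 50%).
#' @return List with `volume` ([pet_volume()] in SUV), `labelmap` (integer
#'   array), `label_table` (data frame label/component), `masks` (named list
#'   of [voi_mask()]), `truth` (data frame), `spec`.
#' @export
generate_phantom <- function(spec, abs_level = 3.0, rel_fraction = 0.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  comps <- spec$components[all_components()]
  labelmap <- array(0L, d)
  values <- array(spec$background_suv, d)
  for (i in seq_along(comps)) {
    m <- solid_mask(comps[[i]]$solid, X, Y, Z)
    if (any(labelmap[m] != 0L))
      stop("component geometries overlap: ", names(comps)[i], call. = FALSE)
    labelmap[m] <- i
    values[m] <- comps[[i]]$suv
  }
  if (!is.null(spec$artifact_rim)) {
    pump <- comps[["pump"]]$solid
    expanded <- pump
    expanded$radius <- pump$radius + spec$artifact_rim$width
    expanded$length <- pump$length + 2 * spec$artifact_rim$width
    rim <- solid_mask(expanded, X, Y, Z) & labelmap == 0L
    values[rim] <- spec$artifact_rim$suv
  }
  if (spec$noise_sigma > 0)
    values <- values + with_seed(spec$seed,
      array(stats::rnorm(length(values), sd = spec$noise_sigma), d))
  values <- gaussian_smooth_3d(values, spec$smoothing_fwhm, sp)

  vol <- pet_volume(values, sp, unit = "SUV")
  label_table <- data.frame(label = seq_along(comps),
                            component = names(comps),
                            stringsAsFactors = FALSE)
  masks <- lapply(seq_along(comps),
                  function(i) voi_mask(which(labelmap == i), names(comps)[i], d))
  names(masks) <- names(comps)

  vv <- prod(sp) / 1000
  truth <- do.call(rbind, lapply(lvad_components(), function(comp) {
    s <- comps[[comp]]$suv
    n_comp <- length(masks[[comp]]$indices)
    per_rule <- function(mode, thr) {
      n <- if (n_comp > 0L && s >= thr) n_comp else 0L
      mean_seg <- if (n > 0L) s else 0
      mtv <- n * vv
      data.frame(component = comp, mode = mode, threshold_applied = thr,
                 n_voxels = n, mtv_cm3 = mtv, suv_mean_seg = mean_seg,
                 tlg = mtv * mean_seg)
    }
    rbind(per_rule("fixed_absolute", abs_level),
          per_rule("fixed_relative", rel_fraction * s))
  }))
  list(volume = vol, labelmap = labelmap, label_table = label_table,
       masks = masks, truth = truth, spec = spec)
}

#' Lesion-metric distribution targets for the two infection groups
#'
#' Default targets for the cohort simulator. SUV-type metrics (SUVmax,
#' SUVmean, SUVpeak, LBR) are specified by median and interquartile range;
#' metabolic-burden metrics (total MTV and total TLG under each threshold
#' rule) by mean and SD. All are positive, right-skewed clinical
#' quantities, modelled log-normally by the generator.
#'
#' @return Data frame with columns `metric`, `group`, `kind`
#'   (`median_iqr` or `mean_sd`), `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
cohort_targets <- function() {
  mk <- function(metric, group, median = NA, q1 = NA, q3 = NA,
                 mean = NA, sd = NA) {
    data.frame(metric = metric, group = group,
               kind = if (is.na(median)) "mean_sd" else "median_iqr",
               median = median, q1 = q1, q3 = q3, mean = mean, sd = sd)
  }
  rbind(
    mk("suv_max", "noninfected", 3.4, 2.15, 4.10),
    mk("suv_max", "infected", 4.85, 3.50, 10.3),
    mk("suv_mean", "noninfected", 1.2, 0.80, 1.90),
    mk("suv_mean", "infected", 1.8, 1.25, 2.70),
    mk("suv_peak", "noninfected", 2.6, 1.72, 3.15),
    mk("suv_peak", "infected", 3.5, 2.55, 6.80),
    mk("lbr", "noninfected", 1.86, 1.27, 2.36),
    mk("lbr", "infected", 3.28, 1.94, 5.12),
    mk("total_mtv_abs", "noninfected", mean = 10.82, sd = 13.65),
    mk("total_mtv_abs", "infected", mean = 44.55, sd = 38.13),
    mk("total_tlg_abs", "noninfected", mean = 39.45, sd = 51.74),
    mk("total_tlg_abs", "infected", mean = 215.42, sd = 201.48),
    mk("total_mtv_rel", "noninfected", mean = 34.61, sd = 12.76),
    mk("total_mtv_rel", "infected", mean = 30.13, sd = 11.38),
    mk("total_tlg_rel", "noninfected", mean = 84.08, sd = 45.49),
    mk("total_tlg_rel", "infected", mean = 108.88, sd = 35.12)
  )
}

# Log-normal parameters matching a target median and IQR ratio: the median
# maps to exp(mu) and the quartile ratio pins sigma.
lnorm_from_median_iqr <- function(median, q1, q3) {
  if (!is.finite(median) || median <= 0) stop("median must be > 0", call. = FALSE)
  if (!is.finite(q1) || !is.finite(q3) || q3 <= q1 || q1 <= 0)
    stop("IQR targets require 0 < q1 < q3", call. = FALSE)
  list(mu = log(median), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# Log-normal parameters matching a target mean and SD (moment equations).
lnorm_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Cohort specification
#'
#' Two-group simulated cohort of per-patient lesion metrics. Each metric is
#' log-normal within a group, with parameters solved in closed form so the
#' distribution's median and IQR (or mean and SD) hit the group's targets.
#' Cross-metric dependence comes from one shared standard-normal latent
#' factor per patient; its loading is chosen so each metric pair attains
#' approximately the requested Spearman rank correlation.
#'
#' @param n_infected,n_noninfected Group sizes (defaults 11 and 6, the
#'   study-cohort sizes the targets describe).
#' @param targets Data frame in the format of [cohort_targets()].
#' @param rho Target pairwise rank correlation between metrics, in
#'   \[0, 1).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_infected = 11L, n_noninfected = 6L,
                        targets = cohort_targets(), rho = 0.5, seed = 1L) {
  stopifnot(n_infected >= 1, n_noninfected >= 1,
            is.data.frame(targets),
            all(c("metric", "group", "kind") %in% names(targets)),
            rho >= 0, rho < 1)
  structure(list(n_infected = as.integer(n_infected),
                 n_noninfected = as.integer(n_noninfected),
                 targets = targets, rho = rho, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a simulated two-group lesion-metric cohort
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `patient_id`, `label` (1 = infected), and one
#'   column per metric in the targets. Deterministic given the spec's seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  metrics <- unique(spec$targets$metric)
  # Gaussian-copula loading achieving Spearman rho between metric pairs
  load <- sqrt(2 * sin(pi * spec$rho / 6))
  gen_group <- function(n, group, prefix) {
    latent <- stats::rnorm(n)
    cols <- lapply(metrics, function(m) {
      tg <- spec$targets[spec$targets$metric == m & spec$targets$group == group, ]
      if (nrow(tg) != 1L)
        stop("need exactly one target row for ", m, " / ", group, call. = FALSE)
      par <- if (tg$kind == "median_iqr")
        lnorm_from_median_iqr(tg$median, tg$q1, tg$q3)
      else lnorm_from_mean_sd(tg$mean, tg$sd)
      z <- load * latent + sqrt(1 - load^2) * stats::rnorm(n)
      exp(par$mu + par$sigma * z)
    })
    names(cols) <- metrics
    data.frame(patient_id = sprintf("%s%04d", prefix, seq_len(n)),
               label = if (group == "infected") 1L else 0L,
               cols, stringsAsFactors = FALSE)
  }
  with_seed(spec$seed, {
    rbind(gen_group(spec$n_infected, "infected", "INF"),
          gen_group(spec$n_noninfected, "noninfected", "NON"))
  })
}
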