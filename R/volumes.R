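#' The five LVAD device components
#'
#' Component identifiers used throughout the package, in the fixed order in
#' which they are reported: the driveline exit site, the driveline within the
#' subcutaneous tissues, the pump housing, the inflow cannula, and the
#' outflow graft. The descending-aorta blood pool is carried alongside as a
#' background reference region but is never counted as a device component.
#'
#' @return Character vector of the five device component names.
#' @export
lvad_components <- function() {
  c("driveline_exit", "driveline_subcutaneous", "pump",
    "inflow_cannula", "outflow_graft")
}

#' @rdname lvad_components
#' @export
background_component <- function() "background_aorta"

all_components <- function() c(lvad_components(), background_component())

#' Construct a PET volume
#'
#' A `pet_volume` is a 3-D scalar grid with voxel spacing in mm and a unit
#' tag. The unit tag travels with the volume: operations that require SUV
#' input check it, so activity-concentration data can never be silently
#' treated as SUV (or normalized twice).
#'
#' @param values 3-D numeric array of voxel values, all finite.
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all > 0.
#' @param unit Either `"kBq_per_mL"` (activity concentration) or `"SUV"`.
#' @return An object of class `pet_volume` with elements `values`, `spacing`,
#'   `unit`.
#' @export
pet_volume <- function(values, spacing, unit = c("kBq_per_mL", "SUV")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3-D volume", call. = FALSE)
  if (length(values) == 0L) stop("volume grid is empty", call. = FALSE)
  if (!all(is.finite(values))) stop("voxel values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, unit = unit),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s, grid %s, spacing %s mm\n",
              x$unit, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

#' Scan metadata
#'
#' Injected dose and body weight needed for body-weight SUV normalization.
#'
#' @param injected_dose Injected activity in MBq, > 0.
#' @param body_weight Body weight in kg, > 0.
#' @param patient_id Opaque patient identifier.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(injected_dose, body_weight, patient_id = "anonymous") {
  injected_dose <- as.numeric(injected_dose)
  body_weight <- as.numeric(body_weight)
  if (length(injected_dose) != 1L || !is.finite(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be a single positive value (MBq)", call. = FALSE)
  if (length(body_weight) != 1L || !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a single positive value (kg)", call. = FALSE)
  structure(list(injected_dose = injected_dose, body_weight = body_weight,
                 patient_id = as.character(patient_id)),
            class = "scan_meta")
}

#' Read a PET volume from a NIfTI file
#'
#' Voxel spacing is taken from the NIfTI header (mm). The value unit comes
#' from the optional sidecar metadata (key `unit`), defaulting to activity
#' concentration in kBq/mL.
#'
#' @param path Path to a 3-D scalar NIfTI image (`.nii` or `.nii.gz`).
#' @param unit Optional unit override; if `NULL`, the sidecar at
#'   `<path without extension>.meta` is consulted, else `"kBq_per_mL"`.
#' @return A [pet_volume()].
#' @export
read_pet_volume <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), " dimensions in ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path, call. = FALSE)
  if (is.null(unit)) {
    side <- sidecar_path(path)
    unit <- if (file.exists(side)) {
      kv <- read_key_value(side)
      if (!is.null(kv[["unit"]])) kv[["unit"]] else "kBq_per_mL"
    } else "kBq_per_mL"
  }
  pet_volume(array(as.numeric(img), dim = d), spacing = sp, unit = unit)
}

#' Write a PET volume (and optional metadata sidecar) to NIfTI
#'
#' @param vol A [pet_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param meta Optional [scan_meta()]; when given, a flat key-value sidecar
#'   (`injected_dose_MBq`, `body_weight_kg`, `unit`) is written next to the
#'   image.
#' @return `path`, invisibly.
#' @export
write_pet_volume <- function(vol, path, meta = NULL) {
  stopifnot(inherits(vol, "pet_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  kv <- c(unit = vol$unit)
  if (!is.null(meta)) {
    stopifnot(inherits(meta, "scan_meta"))
    kv <- c(injected_dose_MBq = format(meta$injected_dose),
            body_weight_kg = format(meta$body_weight),
            patient_id = meta$patient_id, kv)
  }
  write_key_value(kv, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".meta")
}

#' Read scan metadata from a flat key-value sidecar file
#'
#' Expected keys: `injected_dose_MBq`, `body_weight_kg`, optionally
#' `patient_id`.
#'
#' @param path Path to the sidecar text file (`key = value` per line).
#' @return A [scan_meta()].
#' @export
read_scan_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  kv <- read_key_value(path)
  need <- c("injected_dose_MBq", "body_weight_kg")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("metadata file ", path, " is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  scan_meta(as.numeric(kv[["injected_dose_MBq"]]),
            as.numeric(kv[["body_weight_kg"]]),
            if (!is.null(kv[["patient_id"]])) kv[["patient_id"]] else "anonymous")
}

read_key_value <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(parts, function(p) trimws(p[2L]))
  names(out) <- vapply(parts, function(p) trimws(p[1L]), character(1L))
  out
}

write_key_value <- function(kv, path) {
  writeLines(paste(names(kv), unname(kv), sep = " = "), path)
  invisible(path)
}

#' Convert activity concentration to body-weight SUV
#'
#' Per voxel, `SUV = c[kBq/mL] * body_weight[g] / injected_dose[kBq]`,
#' assuming tissue density 1 g/mL and scanner-side decay correction to
#' injection time. Applying this to a volume already in SUV is an error:
#' silent double-normalization is never permitted.
#'
#' @param vol A [pet_volume()] in kBq/mL.
#' @param meta A [scan_meta()].
#' @return A [pet_volume()] in SUV on the same grid.
#' @export
activity_to_suv <- function(vol, meta) {
  stopifnot(inherits(vol, "pet_volume"), inherits(meta, "scan_meta"))
  if (vol$unit != "kBq_per_mL")
    stop("volume is already in ", vol$unit,
         "; refusing to normalize twice", call. = FALSE)
  # weight[g] / dose[kBq] = 1000*kg / (1000*MBq) = kg / MBq
  suv <- vol$values * (meta$body_weight / meta$injected_dose)
  pet_volume(suv, vol$spacing, unit = "SUV")
}

#' Volume of a single voxel in cm^3
#'
#' @param vol A [pet_volume()] with spacing in mm.
#' @return Voxel volume in cm^3 (product of spacings / 1000).
#' @export
voxel_volume <- function(vol) {
  stopifnot(inherits(vol, "pet_volume"))
  prod(vol$spacing) / 1000
}

#' Construct a volume of interest (VOI) mask
#'
#' A `voi_mask` is a set of voxels on a named grid, tagged with the device
#' component (or background role) it delineates. Voxels are stored as 1-based
#' linear indices into the grid array.
#'
#' @param indices Integer vector of linear voxel indices (1-based), within
#'   grid bounds; may be empty for an explicitly absent component.
#' @param component One of [lvad_components()] or `"background_aorta"`.
#' @param grid_dim Integer length-3 grid dimensions the indices refer to.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(indices, component, grid_dim) {
  component <- match.arg(component, all_components())
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim > 0))
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > prod(grid_dim)))
    stop("voxel indices out of grid bounds for component ", component,
         call. = FALSE)
  structure(list(indices = sort(unique(indices)), component = component,
                 grid_dim = grid_dim),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s: %d voxels on %s grid\n", x$component,
              length(x$indices), paste(x$grid_dim, collapse = "x")))
  invisible(x)
}

#' @export
length.voi_mask <- function(x) length(x$indices)

check_same_grid <- function(vol, voi) {
  if (!identical(as.integer(dim(vol$values)), voi$grid_dim))
    stop("VOI grid (", paste(voi$grid_dim, collapse = "x"),
         ") does not match volume grid (",
         paste(dim(vol$values), collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

#' Load component VOI masks from an integer labelmap
#'
#' Builds one [voi_mask()] per mapped label. Labels present in the image but
#' absent from the table are ignored with a warning; a mapped label with no
#' voxels yields an empty mask with a warning. Masks from a single labelmap
#' are pairwise disjoint by construction.
#'
#' @param labelmap Path to an integer NIfTI labelmap, or a 3-D integer array.
#' @param label_table Data frame with columns `label` (distinct non-zero
#'   integers) and `component`, or path to such a two-column CSV.
#' @param vol Optional [pet_volume()]; when supplied, the labelmap grid is
#'   checked against it.
#' @return Named list of [voi_mask()] objects (names are components).
#' @export
load_voi_masks <- function(labelmap, label_table, vol = NULL) {
  if (is.character(labelmap)) {
    if (!file.exists(labelmap))
      stop("labelmap not found: ", labelmap, call. = FALSE)
    img <- RNifti::readNifti(labelmap)
    if (length(dim(img)) != 3L)
      stop("expected 3-D labelmap", call. = FALSE)
    labelmap <- array(as.integer(round(img)), dim = dim(img))
  }
  stopifnot(is.array(labelmap), length(dim(labelmap)) == 3L)
  if (is.character(label_table))
    label_table <- utils::read.csv(label_table, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "component") %in% names(label_table)))
  labs <- as.integer(label_table$label)
  if (anyDuplicated(labs) || any(labs == 0L))
    stop("labels must be distinct non-zero integers", call. = FALSE)
  comps <- as.character(label_table$component)
  if (!all(comps %in% all_components()))
    stop("unknown component(s): ",
         paste(setdiff(comps, all_components()), collapse = ", "),
         call. = FALSE)
  if (!is.null(vol)) {
    stopifnot(inherits(vol, "pet_volume"))
    if (!identical(dim(vol$values), dim(labelmap)))
      stop("labelmap grid (", paste(dim(labelmap), collapse = "x"),
           ") does not match PET grid (",
           paste(dim(vol$values), collapse = "x"), ")", call. = FALSE)
  }
  present <- setdiff(unique(as.vector(labelmap)), 0L)
  unmapped <- setdiff(present, labs)
  if (length(unmapped))
    warning("ignoring unmapped label(s) in image: ",
            paste(sort(unmapped), collapse = ", "), call. = FALSE)
  d <- dim(labelmap)
  masks <- lapply(seq_along(labs), function(i) {
    idx <- which(labelmap == labs[i])
    if (length(idx) == 0L)
      warning("label ", labs[i], " (", comps[i],
              ") has no voxels in the image; mask is empty", call. = FALSE)
    voi_mask(idx, comps[i], d)
  })
  names(masks) <- comps
  masks
}
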