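# Workflow orchestration: simulate -> quantify -> evaluate, with manifests
# for reproducibility. These functions are the package-level interface that
# the thin command-line script in inst/cli/lvadpet.R wraps.

write_manifest <- function(out_dir, workflow, config) {
  kv <- c(workflow = workflow,
          package_version = as.character(utils::packageVersion("lvadpet")),
          vapply(config, function(x) paste(format(x), collapse = ","),
                 character(1L)))
  write_key_value(kv, file.path(out_dir, paste0(workflow, "_manifest.txt")))
}

#' Simulate a phantom and/or a cohort to disk
#'
#' Writes the phantom volume and labelmap as NIfTI with their label table
#' and analytic ground truth as CSV, the simulated cohort as CSV, and a
#' manifest echoing the resolved configuration (including the seeds), so a
#' run is reproducible from its output directory alone.
#'
#' @param out_dir Output directory (created if needed).
#' @param phantom A [phantom_spec()] or `NULL` to skip the phantom.
#' @param cohort A [cohort_spec()] or `NULL` to skip the cohort.
#' @param seed Optional integer overriding both spec seeds (the cohort uses
#'   `seed + 1` so the two products draw distinct streams).
#' @return Named list of written file paths, invisibly.
#' @export
run_simulate <- function(out_dir, phantom = phantom_spec(),
                         cohort = cohort_spec(), seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (!is.null(phantom)) phantom$seed <- seed
    if (!is.null(cohort)) cohort$seed <- seed + 1L
  }
  if (!is.null(phantom)) {
    ph <- generate_phantom(phantom)
    paths$volume <- file.path(out_dir, "phantom_volume.nii.gz")
    write_pet_volume(ph$volume, paths$volume)
    paths$labelmap <- file.path(out_dir, "phantom_labelmap.nii.gz")
    img <- RNifti::asNifti(ph$labelmap)
    RNifti::pixdim(img) <- ph$volume$spacing
    RNifti::writeNifti(img, paths$labelmap, datatype = "int16")
    paths$labels <- file.path(out_dir, "phantom_labels.csv")
    utils::write.csv(ph$label_table, paths$labels, row.names = FALSE)
    paths$truth <- file.path(out_dir, "phantom_ground_truth.csv")
    utils::write.csv(ph$truth, paths$truth, row.names = FALSE)
  }
  if (!is.null(cohort)) {
    paths$cohort <- file.path(out_dir, "cohort.csv")
    utils::write.csv(generate_cohort(cohort), paths$cohort, row.names = FALSE)
  }
  write_manifest(out_dir, "simulate", list(
    phantom_seed = if (!is.null(phantom)) phantom$seed else NA,
    cohort_seed = if (!is.null(cohort)) cohort$seed else NA,
    phantom_shape = if (!is.null(phantom)) phantom$shape else NA,
    noise_sigma = if (!is.null(phantom)) phantom$noise_sigma else NA,
    n_infected = if (!is.null(cohort)) cohort$n_infected else NA,
    n_noninfected = if (!is.null(cohort)) cohort$n_noninfected else NA))
  invisible(paths)
}

#' Quantify one patient's scan from files
#'
#' Reads the PET volume (converting activity concentration to SUV via the
#' metadata sidecar when needed), loads the component masks from the
#' labelmap, and computes the full per-component metrics table.
#'
#' @param volume Path to the PET NIfTI.
#' @param labelmap Path to the integer labelmap NIfTI.
#' @param labels Path to the label,component CSV.
#' @param meta Optional path to the scan-metadata sidecar; defaults to the
#'   volume's own `.meta` sidecar. Required when the volume is in kBq/mL.
#' @param patient_id Identifier; defaults to the sidecar's, else the file
#'   name.
#' @param abs_level,rel_fraction Threshold parameters.
#' @return Metrics data frame as from [quantify_patient()].
#' @export
quantify_files <- function(volume, labelmap, labels, meta = NULL,
                           patient_id = NULL, abs_level = 3.0,
                           rel_fraction = 0.5) {
  vol <- read_pet_volume(volume)
  if (is.null(meta) && file.exists(sidecar_path(volume)))
    meta <- sidecar_path(volume)
  if (vol$unit != "SUV") {
    if (is.null(meta))
      stop("volume ", volume, " is in ", vol$unit,
           " and no metadata file is available for SUV conversion",
           call. = FALSE)
    vol <- activity_to_suv(vol, read_scan_meta(meta))
  }
  if (is.null(patient_id)) {
    patient_id <- if (!is.null(meta) && file.exists(meta)) {
      kv <- read_key_value(meta)
      if (!is.null(kv[["patient_id"]])) kv[["patient_id"]]
      else basename(volume)
    } else basename(volume)
  }
  vois <- load_voi_masks(labelmap, labels, vol)
  quantify_patient(vol, vois, patient_id = patient_id,
                   abs_level = abs_level, rel_fraction = rel_fraction)
}

#' Quantify a batch of patients
#'
#' Per-patient failures are logged as warnings and skipped; the summary
#' reports them so callers (and the CLI's exit code) can distinguish a
#' clean run from a partial one.
#'
#' @param patients Data frame with columns `volume`, `labelmap`, `labels`
#'   and optionally `meta`, `patient_id`; one row per patient.
#' @param out_csv Optional path for the combined metrics CSV.
#' @param abs_level,rel_fraction Threshold parameters.
#' @return List with `metrics` (combined data frame) and `failures`
#'   (character vector of failed volume paths), invisibly when writing.
#' @export
run_quantify <- function(patients, out_csv = NULL, abs_level = 3.0,
                         rel_fraction = 0.5) {
  stopifnot(is.data.frame(patients),
            all(c("volume", "labelmap", "labels") %in% names(patients)))
  results <- list()
  failures <- character()
  for (i in seq_len(nrow(patients))) {
    row <- patients[i, ]
    res <- tryCatch(
      quantify_files(row$volume, row$labelmap, row$labels,
                     meta = if ("meta" %in% names(patients)) row$meta else NULL,
                     patient_id = if ("patient_id" %in% names(patients))
                       row$patient_id else NULL,
                     abs_level = abs_level, rel_fraction = rel_fraction),
      error = function(e) {
        warning("patient ", row$volume, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) failures <- c(failures, row$volume)
    else results[[length(results) + 1L]] <- res
  }
  metrics <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(out_csv) && !is.null(metrics))
    utils::write.csv(metrics, out_csv, row.names = FALSE)
  out <- list(metrics = metrics, failures = failures)
  if (!is.null(out_csv)) invisible(out) else out
}

#' Evaluate cohort diagnostics
#'
#' Runs the full diagnostic battery on a cohort table: per-metric ROC with
#' DeLong AUC interval, Youden cutoff and prevalence-adjusted predictive
#' values; the pairwise DeLong AUC-comparison matrix; and the two-group
#' comparison table.
#'
#' @param cohort Data frame or path to a cohort CSV with a binary label
#'   column.
#' @param metrics Metric columns to evaluate; default: every numeric
#'   non-label column.
#' @param label_col Binary label column name (1 = infected).
#' @param prevalence Assumed prevalence for predictive values (default 0.6).
#' @param level AUC confidence level (default 0.95).
#' @param out_dir Optional directory; when given, writes `roc_report.csv`,
#'   `delong_pvalues.csv`, `group_comparison.csv` and a manifest.
#' @return List with `roc_report`, `delong_pvalues`, `group_comparison`.
#' @export
run_evaluate <- function(cohort, metrics = NULL, label_col = "label",
                         prevalence = 0.6, level = 0.95, out_dir = NULL) {
  if (is.character(cohort))
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(cohort), label_col %in% names(cohort))
  if (is.null(metrics)) {
    num <- vapply(cohort, is.numeric, logical(1L))
    metrics <- setdiff(names(cohort)[num], c(label_col, "patient_id"))
  }
  report <- evaluate_metrics(cohort, metrics, label_col,
                             prevalence = prevalence, level = level)
  dmat <- delong_matrix(cohort, metrics, label_col)
  comparison <- compare_cohort(cohort, metrics, label_col)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "roc_report.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dmat),
                     file.path(out_dir, "delong_pvalues.csv"))
    utils::write.csv(comparison, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "evaluate",
                   list(metrics = metrics, label_col = label_col,
                        prevalence = prevalence, ci_level = level))
  }
  list(roc_report = report, delong_pvalues = dmat,
       group_comparison = comparison)
}
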