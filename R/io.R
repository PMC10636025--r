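#' Write an image volume to a NIfTI file
#'
#' Voxels are stored as 64-bit doubles so that write-then-read round-trips
#' are lossless. Modality and limb axis, which NIfTI has no standard slot
#' for, go into a JSON sidecar next to the image (`<path>.json`).
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(modality = vol$modality, limb_axis = vol$limb_axis),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an image volume from a NIfTI file
#'
#' Spacing is taken from the NIfTI pixdim. Modality and limb axis come from
#' the JSON sidecar written by [write_volume()] when present; otherwise
#' `modality` falls back to the argument, and failing that is inferred from
#' the voxel values (any value below -500 reads as CT air, hence CT).
#'
#' @param path path to a readable NIfTI file.
#' @param modality optional override, `"CT"` or `"SPECT"`.
#' @param limb_axis optional override for the proximal-to-distal axis.
#' @return An [image_volume].
#' @export
read_volume <- function(path, modality = NULL, limb_axis = NULL) {
  if (!file.exists(path))
    stop("volume file does not exist: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read '", path, "' as NIfTI: ",
                         conditionMessage(e), call. = FALSE))
  voxels <- as.array(img)
  if (length(dim(voxels)) != 3)
    stop("expected a 3-D volume in ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(modality))
    modality <- meta$modality %||%
      (if (min(voxels, na.rm = TRUE) < -500) "CT" else "SPECT")
  if (is.null(limb_axis)) limb_axis <- meta$limb_axis %||% 3L
  image_volume(voxels, spacing, modality = modality,
               limb_axis = as.integer(limb_axis))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort table of patient records
#'
#' Reads a delimited table with one row per patient. Required columns:
#' `id`, `extremity` (upper/lower), `side` (left/right), `duration_months`
#' (non-negative), `contamination_flag` (logical). Any further columns
#' (age, sex, BMI, ISL stage, ...) are carried through untouched as labels.
#' A derived logical column `chronic` is added: lymphedema duration of at
#' least 12 months classifies a patient as chronic (inclusive boundary).
#'
#' @param path path to a CSV file with a header row.
#' @return A `data.frame` of patient records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path))
    stop("cohort table does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "extremity", "side", "duration_months",
                "contamination_flag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$duration_months <- as.numeric(df$duration_months)
  if (any(!is.finite(df$duration_months)) || any(df$duration_months < 0))
    stop("duration_months must be non-negative numbers", call. = FALSE)
  bad <- !tolower(df$extremity) %in% c("upper", "lower")
  if (any(bad))
    stop("extremity must be 'upper' or 'lower' (rows: ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  df$contamination_flag <- as.logical(df$contamination_flag)
  df$chronic <- is_chronic(df$duration_months)
  df
}

#' Chronicity from lymphedema duration
#'
#' @param duration_months numeric vector of durations in months.
#' @return Logical: `TRUE` when duration is 12 months or more.
#' @export
is_chronic <- function(duration_months) duration_months >= 12

#' Write a phantom study to disk in the pipeline's native layout
#'
#' Writes the affected CT/SPECT pair and the unaffected CT as NIfTI (plus
#' sidecars), the exclusion mask, and the patient record as a one-row CSV.
#'
#' @param study a study list as produced by [generate_cohort()] (elements
#'   `ct_affected`, `spect_affected`, `ct_unaffected`, `exclusion_mask`,
#'   `record`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(study$ct_affected, file.path(dir, "ct_affected.nii.gz"))
  write_volume(study$spect_affected, file.path(dir, "spect_affected.nii.gz"))
  write_volume(study$ct_unaffected, file.path(dir, "ct_unaffected.nii.gz"))
  excl <- image_volume(study$exclusion_mask + 0,
                       study$ct_affected$spacing, "CT",
                       study$ct_affected$limb_axis)
  write_volume(excl, file.path(dir, "exclusion_mask.nii.gz"))
  utils::write.csv(study$record, file.path(dir, "record.csv"),
                   row.names = FALSE)
  invisible(dir)
}
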