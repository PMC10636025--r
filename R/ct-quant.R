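#' Configuration of the CT quantification chain
#'
#' The segmentation thresholds mirror conventional radiology values: the
#' limb is everything above an air/soft-tissue cut grown from a seed, bone
#' is high-attenuation tissue with morphological closing, muscle is the
#' soft-tissue Hounsfield window restricted to the compact interior region
#' (the largest connected component, which excludes stray subcutaneous
#' voxels), and the honeycomb window on the SC compartment is inclusive on
#' both bounds.
#'
#' @param limb_hu_min HU above which a voxel can belong to the limb during
#'   region growing (default -300; air stays out, fat stays in).
#' @param bone_hu_min HU at or above which a voxel is bone (default 150).
#' @param muscle_hu inclusive HU window for muscle (default \[20, 100\]).
#' @param hp_window inclusive HU window delimiting the honeycomb pattern in
#'   the SC compartment (default \[-60, 10\]).
#' @param closing_iter iterations of 6-connected morphological closing
#'   applied to the bone and muscle masks.
#' @param crop_fractions length-2 fractions of the limb axis cropped at the
#'   proximal and distal ends (anatomical boundary handling; phantoms use
#'   the full axis).
#' @param connectivity voxel connectivity for region growing (6 or 26).
#' @return Object of class `ct_quant_config`.
#' @export
ct_quant_config <- function(limb_hu_min = -300, bone_hu_min = 150,
                            muscle_hu = c(20, 100), hp_window = c(-60, 10),
                            closing_iter = 1L, crop_fractions = c(0, 0),
                            connectivity = 6L) {
  stopifnot(is.finite(limb_hu_min), is.finite(bone_hu_min),
            length(muscle_hu) == 2, muscle_hu[1] < muscle_hu[2],
            length(hp_window) == 2, all(is.finite(hp_window)),
            length(crop_fractions) == 2, all(crop_fractions >= 0),
            sum(crop_fractions) < 1, connectivity %in% c(6L, 26L))
  if (hp_window[1] >= hp_window[2])
    stop("hp window must satisfy hp_lo < hp_hi", call. = FALSE)
  structure(list(limb_hu_min = limb_hu_min, bone_hu_min = bone_hu_min,
                 muscle_hu = as.numeric(muscle_hu),
                 hp_window = as.numeric(hp_window),
                 closing_iter = as.integer(closing_iter),
                 crop_fractions = as.numeric(crop_fractions),
                 connectivity = as.integer(connectivity)),
            class = "ct_quant_config")
}

#' Segment the limb from CT by seeded region growing
#'
#' Grows the connected set of voxels above the air/soft-tissue threshold
#' that contains the seed, then crops to the configured extremity
#' boundaries along the limb axis. The result is a single connected
#' component excluding the air background.
#'
#' @param ct an [image_volume] of modality CT.
#' @param seed_point voxel index triple (1-based) inside soft tissue, or
#'   `NULL` to seed automatically at the brightest voxel (bone).
#' @param cfg a [ct_quant_config()].
#' @return Logical mask array.
#' @export
segment_limb <- function(ct, seed_point = NULL, cfg = ct_quant_config()) {
  stopifnot(inherits(ct, "image_volume"))
  hu <- ct$voxels
  d <- dim(hu)
  if (is.null(seed_point)) {
    seed_point <- arrayInd(which.max(hu), d)[1, ]
  }
  seed_point <- as.integer(seed_point)
  stopifnot(length(seed_point) == 3, all(seed_point >= 1),
            all(seed_point <= d))
  if (hu[seed_point[1], seed_point[2], seed_point[3]] <= cfg$limb_hu_min)
    stop("seed point lies in air (HU <= ", cfg$limb_hu_min,
         "); place it inside soft tissue", call. = FALSE)
  cand <- hu > cfg$limb_hu_min
  ax <- ct$limb_axis
  nz <- d[ax]
  lo <- as.integer(floor(nz * cfg$crop_fractions[1]))
  hi <- nz - as.integer(floor(nz * cfg$crop_fractions[2]))
  if (lo > 0 || hi < nz) {
    idx <- slice.index(cand, ax)
    cand <- cand & idx > lo & idx <= hi
  }
  lab <- label_components(cand, cfg$connectivity)
  seed_lab <- lab[seed_point[1], seed_point[2], seed_point[3]]
  if (seed_lab == 0)
    stop("seed point was cropped out of the extremity boundaries",
         call. = FALSE)
  lab == seed_lab
}

#' Segment bone, muscle and subcutaneous compartments
#'
#' Bone and muscle are thresholded inside the limb and cleaned by
#' morphological closing; muscle keeps only the largest connected component
#' (the muscle belly interior to the subcutaneous fat ring). The SC
#' compartment is obtained by subtracting the segmented muscle and bone
#' from the segmented extremity, and the returned object enforces that
#' identity exactly.
#'
#' @param ct an [image_volume] of modality CT.
#' @param limb_mask logical limb mask from [segment_limb()].
#' @param cfg a [ct_quant_config()].
#' @return A [compartment_masks] object.
#' @export
segment_compartments <- function(ct, limb_mask, cfg = ct_quant_config()) {
  stopifnot(inherits(ct, "image_volume"), is.logical(limb_mask),
            identical(dim(limb_mask), dim(ct$voxels)))
  if (!any(limb_mask))
    stop("limb mask is empty", call. = FALSE)
  hu <- ct$voxels
  bone <- hu >= cfg$bone_hu_min & limb_mask
  if (any(bone) && cfg$closing_iter > 0)
    bone <- close_mask(bone, cfg$closing_iter) & limb_mask
  musc <- hu >= cfg$muscle_hu[1] & hu <= cfg$muscle_hu[2] & limb_mask & !bone
  if (any(musc)) {
    if (cfg$closing_iter > 0)
      musc <- close_mask(musc, cfg$closing_iter) & limb_mask & !bone
    lab <- label_components(musc, cfg$connectivity)
    sizes <- tabulate(lab[lab > 0])
    musc <- lab == which.max(sizes)
  }
  compartment_masks(limb_mask, bone, musc)
}

#' Volume of a mask in cubic centimetres
#'
#' @param mask logical array.
#' @param spacing voxel spacing (mm).
#' @return `sum(mask) * dx*dy*dz / 1000` in cm^3.
#' @export
compute_volume <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(spacing) == 3, all(spacing > 0))
  sum(mask) * voxel_volume_mm3(spacing) / 1000
}

#' Honeycomb-pattern volume ratio in the subcutaneous compartment
#'
#' The HP mask is the set of SC voxels whose HU falls inside the honeycomb
#' window (both bounds inclusive). The HP volume ratio is the HP volume
#' divided by the SC volume.
#'
#' @param ct an [image_volume] of modality CT.
#' @param sc_mask logical SC mask; must be non-empty.
#' @param cfg a [ct_quant_config()].
#' @return List with `hp_mask`, `hp_volume_cm3`, `sc_volume_cm3` and
#'   `hp_ratio` (in \[0, 1\]).
#' @export
hp_ratio <- function(ct, sc_mask, cfg = ct_quant_config()) {
  stopifnot(inherits(ct, "image_volume"), is.logical(sc_mask),
            identical(dim(sc_mask), dim(ct$voxels)))
  if (!any(sc_mask))
    stop("SC mask is empty: HP ratio is undefined", call. = FALSE)
  w <- cfg$hp_window
  hp_mask <- sc_mask & ct$voxels >= w[1] & ct$voxels <= w[2]
  vox <- voxel_volume_mm3(ct$spacing) / 1000
  list(hp_mask = hp_mask,
       hp_volume_cm3 = sum(hp_mask) * vox,
       sc_volume_cm3 = sum(sc_mask) * vox,
       hp_ratio = sum(hp_mask) / sum(sc_mask))
}

# Severity grade from the CT volumetric difference percent. Bands are
# half-open: [10,20) -> 1, [20,30) -> 2, [30,40) -> 3, [40,Inf) -> 4;
# anything below 10 (including negative differences) is Grade 0.
grade_from_percent <- function(percent) {
  findInterval(percent, c(10, 20, 30, 40))
}

#' CT volumetric difference and severity grade
#'
#' The volumetric difference is the affected minus unaffected limb volume,
#' divided by the unaffected volume, times 100. Severity grades: Grade 0
#' below 10%, Grade 1 in \[10, 20), Grade 2 in \[20, 30), Grade 3 in
#' \[30, 40), Grade 4 at 40% and above. A negative difference (affected
#' limb smaller) clamps to Grade 0 with a warning.
#'
#' @param v_affected_cm3,v_unaffected_cm3 total limb volumes in cm^3; the
#'   unaffected volume must be positive.
#' @return List with `v_affected_cm3`, `v_unaffected_cm3`,
#'   `ct_diff_percent` and `severity_grade` (0-4).
#' @export
volumetric_grade <- function(v_affected_cm3, v_unaffected_cm3) {
  if (!is.finite(v_unaffected_cm3) || v_unaffected_cm3 <= 0)
    stop("unaffected limb volume must be positive", call. = FALSE)
  if (!is.finite(v_affected_cm3) || v_affected_cm3 < 0)
    stop("affected limb volume must be non-negative", call. = FALSE)
  pct <- 100 * (v_affected_cm3 - v_unaffected_cm3) / v_unaffected_cm3
  if (pct < 0)
    warning("affected limb is smaller than the unaffected limb (",
            round(pct, 1), "%); grading as Grade 0", call. = FALSE)
  list(v_affected_cm3 = v_affected_cm3,
       v_unaffected_cm3 = v_unaffected_cm3,
       ct_diff_percent = pct,
       severity_grade = grade_from_percent(pct))
}
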