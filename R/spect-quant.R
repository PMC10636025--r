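#' Configuration of the SPECT dermal-backflow extraction
#'
#' The DBF volume of interest is grown by 3-D iso-contouring: from each
#' seed, the connected set of voxels whose activity reaches a fixed
#' fraction of the seed-connected maximum. Auto-seeding picks the brightest
#' SC voxel per limb region outside the exclusion masks; a seed is only
#' accepted when its activity clears a background gate, so regions without
#' dermal backflow yield no VOI.
#'
#' @param iso_fraction iso-contour threshold as a fraction of the
#'   seed-connected maximum, in (0, 1); default 0.10.
#' @param min_volume_cm3 VOI components smaller than this are dropped, and
#'   a region with less than this DBF volume counts as DBF-absent
#'   (default 1 cm^3; suppresses noise speckle).
#' @param split_fraction proximal/distal split plane for auto-seeding and
#'   extent calls.
#' @param seed_gate_median_factor,seed_gate_fraction a candidate seed is
#'   accepted when its activity is at least
#'   `max(seed_gate_median_factor * background, seed_gate_fraction *
#'   maximum activity)`, where the background level is the median activity
#'   of the non-zero deep-tissue voxels (outside the SC compartment, which
#'   stays clean however widespread the dermal backflow is). The
#'   maximum-fraction term keeps smoothed hotspot tails (injection depot,
#'   nodes) from seeding spurious VOIs.
#' @param connectivity voxel connectivity (6 or 26).
#' @return Object of class `dbf_config`.
#' @export
dbf_config <- function(iso_fraction = 0.10, min_volume_cm3 = 1.0,
                       split_fraction = 0.5,
                       seed_gate_median_factor = 5,
                       seed_gate_fraction = 0.05,
                       connectivity = 6L) {
  if (!is.numeric(iso_fraction) || iso_fraction <= 0 || iso_fraction >= 1)
    stop("iso_fraction must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(min_volume_cm3 >= 0, split_fraction > 0, split_fraction < 1,
            seed_gate_median_factor >= 0, seed_gate_fraction >= 0,
            connectivity %in% c(6L, 26L))
  structure(list(iso_fraction = iso_fraction,
                 min_volume_cm3 = min_volume_cm3,
                 split_fraction = split_fraction,
                 seed_gate_median_factor = seed_gate_median_factor,
                 seed_gate_fraction = seed_gate_fraction,
                 connectivity = as.integer(connectivity)),
            class = "dbf_config")
}

#' Extract the dermal-backflow VOI by 3-D iso-contour region growing
#'
#' For each seed the seed-connected maximum is found iteratively: the
#' threshold is set to `iso_fraction` times the current maximum, the
#' connected super-threshold component containing the seed is grown over
#' the volume minus the exclusion masks, and the maximum is updated until
#' it stabilises. The union over seeds is intersected with the SC
#' compartment (dermal backflow lives in the subcutis) and connected
#' components below the minimum volume are dropped.
#'
#' @param spect an [image_volume] of modality SPECT.
#' @param seed_points `NULL` for auto-seeding (brightest SC voxel per limb
#'   region outside exclusions, subject to the background gate), or a
#'   matrix/vector of 1-based voxel index triples (one row per seed).
#'   Manual seeds below the background gate raise an error.
#' @param sc_mask logical SC mask of the affected limb.
#' @param cfg a [dbf_config()].
#' @param exclusion_mask optional logical array removing the injection-site
#'   depot and nodal/duct hotspots from the VOI.
#' @return Logical DBF mask, with attribute `seeds` (the accepted seed
#'   voxel indices, possibly zero rows).
#' @export
extract_dbf <- function(spect, seed_points = NULL, sc_mask,
                        cfg = dbf_config(), exclusion_mask = NULL) {
  stopifnot(inherits(spect, "image_volume"), is.logical(sc_mask),
            identical(dim(sc_mask), dim(spect$voxels)))
  act <- spect$voxels
  d <- dim(act)
  if (is.null(exclusion_mask)) {
    exclusion_mask <- array(FALSE, d)
  } else {
    stopifnot(is.logical(exclusion_mask), identical(dim(exclusion_mask), d))
  }
  # Background from deep tissue: SC activity is not usable as a background
  # reference because entire-limb dermal backflow can fill most of it.
  bg <- act[!sc_mask & act > 0]
  bg_level <- if (length(bg)) median(bg) else median(act[sc_mask])
  gate <- max(cfg$seed_gate_median_factor * bg_level,
              cfg$seed_gate_fraction * max(act))

  if (is.null(seed_points)) {
    regs <- region_masks(sc_mask, cfg$split_fraction, spect$limb_axis)
    seeds <- list()
    for (reg in regs) {
      cand <- which(reg & !exclusion_mask)
      if (!length(cand)) next
      best <- cand[which.max(act[cand])]
      if (act[best] >= gate) seeds[[length(seeds) + 1]] <- best
    }
    seeds <- unlist(seeds)
  } else {
    sp <- seed_points
    if (is.vector(sp)) sp <- matrix(sp, nrow = 1)
    stopifnot(ncol(sp) == 3)
    seeds <- sp[, 1] + (sp[, 2] - 1) * d[1] + (sp[, 3] - 1) * d[1] * d[2]
    low <- act[seeds] < gate
    if (any(low))
      stop("seed(s) below the background activity gate (",
           signif(gate, 4), "): ",
           paste(which(low), collapse = ", "), call. = FALSE)
    excl_seed <- exclusion_mask[seeds]
    if (any(excl_seed))
      stop("seed(s) inside an exclusion mask: ",
           paste(which(excl_seed), collapse = ", "), call. = FALSE)
  }

  out <- array(FALSE, d)
  for (s in seeds) {
    m <- act[s]
    comp <- NULL
    repeat {
      thr <- cfg$iso_fraction * m
      cand <- act >= thr & !exclusion_mask
      lab <- label_components(cand, cfg$connectivity)
      comp <- lab == lab[s]
      m_new <- max(act[comp])
      if (m_new <= m) break
      m <- m_new
    }
    out <- out | comp
  }
  out <- out & sc_mask
  if (any(out) && cfg$min_volume_cm3 > 0) {
    vox_cm3 <- voxel_volume_mm3(spect$spacing) / 1000
    lab <- label_components(out, cfg$connectivity)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * vox_cm3 >= cfg$min_volume_cm3)
    out <- array(lab %in% keep & lab > 0, d)
  }
  attr(out, "seeds") <- if (length(seeds))
    arrayInd(seeds, d) else matrix(integer(0), 0, 3)
  out
}

#' Dermal-backflow volume ratio
#'
#' The DBF volume divided by the SC volume of the affected extremity.
#'
#' @param dbf_mask logical DBF mask.
#' @param sc_volume_cm3 SC volume of the affected limb (cm^3, positive).
#' @param spacing voxel spacing (mm).
#' @return List with `dbf_volume_cm3` and `dbf_ratio`.
#' @export
dbf_ratio <- function(dbf_mask, sc_volume_cm3, spacing) {
  stopifnot(is.logical(dbf_mask))
  if (!is.finite(sc_volume_cm3) || sc_volume_cm3 <= 0)
    stop("SC volume must be positive", call. = FALSE)
  v <- compute_volume(dbf_mask, spacing)
  list(dbf_volume_cm3 = v, dbf_ratio = v / sc_volume_cm3)
}

#' Per-region dermal-backflow extent
#'
#' DBF counts as present in a region when the DBF volume inside that region
#' reaches the minimum VOI volume. The extent is `none`, `proximal`,
#' `distal`, or `entire` (both regions).
#'
#' @param dbf_mask logical DBF mask.
#' @param regions named list of two disjoint logical region masks
#'   (`proximal`, `distal`), e.g. from [region_masks()].
#' @param spacing voxel spacing (mm).
#' @param cfg a [dbf_config()].
#' @return List with `extent`, `presence` (named logical) and
#'   `region_volume_cm3` (named numeric).
#' @export
dbf_extent <- function(dbf_mask, regions, spacing, cfg = dbf_config()) {
  stopifnot(is.logical(dbf_mask), is.list(regions),
            all(c("proximal", "distal") %in% names(regions)))
  if (any(regions$proximal & regions$distal))
    stop("region masks overlap; they must partition the limb",
         call. = FALSE)
  vols <- vapply(regions[c("proximal", "distal")],
                 function(r) compute_volume(dbf_mask & r, spacing),
                 numeric(1))
  presence <- vols >= cfg$min_volume_cm3
  list(extent = dbf_flags_to_extent(presence[["proximal"]],
                                    presence[["distal"]]),
       presence = presence,
       region_volume_cm3 = vols)
}
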