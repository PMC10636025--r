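#' Specification of a synthetic limb phantom
#'
#' Describes one limb as a tapered cylinder along the limb axis with
#' concentric bone, muscle and subcutaneous (SC) compartments, each with its
#' own Hounsfield distribution; a honeycomb-pattern (HP) texture fraction
#' inside the SC fat; a dermal-backflow (DBF) activity rim on SPECT confined
#' to the proximal and/or distal half; nodal, duct and injection-depot
#' hotspots; and the acquisition noise model (Gaussian for CT, a Gaussian
#' point-spread function followed by Poisson counting for SPECT). The seed
#' fully determines the generated volumes.
#'
#' HP texture is laid down as a smoothed Gaussian random field thresholded
#' per region at exactly the target voxel count, which yields connected
#' strand-like structures rather than independent voxel salt.
#'
#' @param extremity `"lower"` or `"upper"` (metadata only; the geometry is
#'   the same tapered cylinder).
#' @param dims grid dimensions (3 integers); the limb axis is axis 3.
#' @param spacing voxel spacing in mm.
#' @param radius_mm limb radius at the proximal end.
#' @param taper distal radius as a fraction of the proximal radius.
#' @param volume_scale multiplies the limb cross-sectional area (radius by
#'   its square root); used to inflate the affected limb for volumetry.
#' @param bone_frac,muscle_frac outer radii of bone and muscle as fractions
#'   of the local limb radius; must satisfy 0 <= bone_frac < muscle_frac < 1.
#' @param hu_mean,hu_sd named numeric vectors (`bone`, `muscle`, `fat`,
#'   `air`) of Hounsfield means and tissue-heterogeneity SDs.
#' @param hp_fraction length-2 (proximal, distal) target fraction of SC
#'   voxels carrying HP-texture values, each in \[0, 1\]. HP voxels get HU
#'   drawn uniformly inside `hp_window`.
#' @param hp_window HU window delimiting the honeycomb texture (inclusive).
#' @param hp_texture_mm smoothing length of the HP random field (strand
#'   scale).
#' @param dbf length-2 logical (proximal, distal): paint a dermal activity
#'   rim in that region.
#' @param dbf_rim_mm thickness of the dermal rim, measured inward from the
#'   skin surface.
#' @param dbf_activity rim activity (arbitrary units, relative to
#'   `background_activity`).
#' @param dbf_split_margin_mm,dbf_edge_margin_mm,dbf_depot_margin_mm axial
#'   standoff of the rim from the region split plane, the proximal limb end,
#'   and the distal injection site, so that hotspot and cross-region blur do
#'   not overlap the rim.
#' @param node_proximal,node_intermediate,duct logical hotspot switches
#'   (proximal lymph node, intermediate lymph node, linear lymphatic duct).
#' @param node_activity,duct_activity hotspot activities.
#' @param injection_depot paint the intradermal injection depot at the
#'   distal end.
#' @param depot_activity depot activity.
#' @param background_activity soft-tissue background activity inside the
#'   limb.
#' @param ct_noise_sd additive Gaussian CT noise (HU).
#' @param spect_fwhm_mm isotropic Gaussian PSF applied to the activity map
#'   before Poisson sampling.
#' @param spect_count_scale expected counts per activity unit; Poisson
#'   counts are drawn at `lambda = activity * spect_count_scale`.
#' @param hotspot_exclusion_mm,depot_exclusion_mm dilation of the nodal/duct
#'   and depot hotspots used to build the ground-truth exclusion mask handed
#'   to the DBF extraction.
#' @param split_fraction fractional position of the proximal/distal split
#'   plane along the limb axis.
#' @param hp_presence_threshold regional HP fraction at or above which the
#'   ground-truth pattern counts the region as HP-positive.
#' @param seed integer RNG seed; the same spec and seed give bit-identical
#'   volumes.
#' @return Object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(extremity = c("lower", "upper"),
                         dims = c(96L, 96L, 96L),
                         spacing = c(2, 2, 2),
                         radius_mm = 40,
                         taper = 0.8,
                         volume_scale = 1,
                         bone_frac = 0.15,
                         muscle_frac = 0.65,
                         hu_mean = c(bone = 700, muscle = 50, fat = -100,
                                     air = -1000),
                         hu_sd = c(bone = 100, muscle = 10, fat = 15,
                                   air = 20),
                         hp_fraction = c(proximal = 0, distal = 0),
                         hp_window = c(-60, 10),
                         hp_texture_mm = 4,
                         dbf = c(proximal = FALSE, distal = FALSE),
                         dbf_rim_mm = 12,
                         dbf_activity = 30,
                         dbf_split_margin_mm = 12,
                         dbf_edge_margin_mm = 8,
                         dbf_depot_margin_mm = 32,
                         node_proximal = TRUE,
                         node_intermediate = FALSE,
                         duct = TRUE,
                         node_activity = 40,
                         duct_activity = 5,
                         injection_depot = TRUE,
                         depot_activity = 60,
                         background_activity = 0.05,
                         ct_noise_sd = 3,
                         spect_fwhm_mm = 12,
                         spect_count_scale = 20,
                         hotspot_exclusion_mm = 12,
                         depot_exclusion_mm = 18,
                         split_fraction = 0.5,
                         hp_presence_threshold = 0.05,
                         seed = 1L) {
  extremity <- match.arg(extremity)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 8),
            length(spacing) == 3, all(spacing > 0),
            radius_mm > 0, taper > 0, taper <= 1, volume_scale > 0)
  if (!(bone_frac >= 0 && bone_frac < muscle_frac && muscle_frac < 1))
    stop("compartment radii fractions must satisfy ",
         "0 <= bone_frac < muscle_frac < 1", call. = FALSE)
  hp_fraction <- rep_len(as.numeric(hp_fraction), 2)
  names(hp_fraction) <- c("proximal", "distal")
  if (any(hp_fraction < 0) || any(hp_fraction > 1))
    stop("hp_fraction must lie in [0, 1]", call. = FALSE)
  dbf <- rep_len(as.logical(dbf), 2)
  names(dbf) <- c("proximal", "distal")
  stopifnot(hp_window[1] < hp_window[2], split_fraction > 0,
            split_fraction < 1, background_activity > 0,
            dbf_activity > 0, spect_count_scale > 0, ct_noise_sd >= 0)
  spec <- list(
    extremity = extremity, dims = dims, spacing = as.numeric(spacing),
    radius_mm = radius_mm, taper = taper, volume_scale = volume_scale,
    bone_frac = bone_frac, muscle_frac = muscle_frac,
    hu_mean = hu_mean, hu_sd = hu_sd,
    hp_fraction = hp_fraction, hp_window = as.numeric(hp_window),
    hp_texture_mm = hp_texture_mm,
    dbf = dbf, dbf_rim_mm = dbf_rim_mm, dbf_activity = dbf_activity,
    dbf_split_margin_mm = dbf_split_margin_mm,
    dbf_edge_margin_mm = dbf_edge_margin_mm,
    dbf_depot_margin_mm = dbf_depot_margin_mm,
    node_proximal = node_proximal, node_intermediate = node_intermediate,
    duct = duct, node_activity = node_activity,
    duct_activity = duct_activity,
    injection_depot = injection_depot, depot_activity = depot_activity,
    background_activity = background_activity,
    ct_noise_sd = ct_noise_sd, spect_fwhm_mm = spect_fwhm_mm,
    spect_count_scale = spect_count_scale,
    hotspot_exclusion_mm = hotspot_exclusion_mm,
    depot_exclusion_mm = depot_exclusion_mm,
    split_fraction = split_fraction,
    hp_presence_threshold = hp_presence_threshold,
    seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Local limb radius (mm) at each slice centre along the limb axis.
phantom_radii <- function(spec) {
  nz <- spec$dims[3]
  z_mm <- (seq_len(nz) - 0.5) * spec$spacing[3]
  len <- nz * spec$spacing[3]
  spec$radius_mm * (1 - (1 - spec$taper) * z_mm / len) *
    sqrt(spec$volume_scale)
}

# Paint `value` into `arr` inside a sphere given in mm coordinates
# (x and y measured from the grid centre, z from the proximal face).
paint_sphere <- function(arr, spec, centre_mm, radius_mm, value) {
  d <- spec$dims
  sp <- spec$spacing
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  z_mm <- (seq_len(d[3]) - 0.5) * sp[3]
  for (k in which(abs(z_mm - centre_mm[3]) <= radius_mm)) {
    r2 <- radius_mm^2 - (z_mm[k] - centre_mm[3])^2
    disc <- outer((x - centre_mm[1])^2, (y - centre_mm[2])^2, `+`) <= r2
    slab <- arr[, , k]
    slab[disc] <- value
    arr[, , k] <- slab
  }
  arr
}

# Paint a duct-like cylinder running along the limb axis at a fractional
# radial offset of the local limb radius.
paint_duct <- function(arr, spec, radii, offset_frac, radius_mm, z_range_mm,
                       value) {
  d <- spec$dims
  sp <- spec$spacing
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  z_mm <- (seq_len(d[3]) - 0.5) * sp[3]
  for (k in which(z_mm >= z_range_mm[1] & z_mm <= z_range_mm[2])) {
    ox <- offset_frac * radii[k]
    disc <- outer((x - ox)^2, y^2, `+`) <= radius_mm^2
    slab <- arr[, , k]
    slab[disc] <- value
    arr[, , k] <- slab
  }
  arr
}

# Deterministic geometry of a phantom: compartment masks, region split and
# the dermal-rim masks for the regions flagged in `spec$dbf`. No RNG.
phantom_masks <- function(spec) {
  d <- spec$dims
  sp <- spec$spacing
  nz <- d[3]
  len <- nz * sp[3]
  z_mm <- (seq_len(nz) - 0.5) * sp[3]
  radii <- phantom_radii(spec)
  r2 <- plane_r2(d, sp)

  limb <- bone <- muscle <- array(FALSE, d)
  for (k in seq_len(nz)) {
    limb[, , k] <- r2 <= radii[k]^2
    if (spec$bone_frac > 0)
      bone[, , k] <- r2 <= (spec$bone_frac * radii[k])^2
    muscle[, , k] <- r2 <= (spec$muscle_frac * radii[k])^2 & !bone[, , k]
  }
  masks <- compartment_masks(limb, bone, muscle)
  regions <- region_masks(limb, spec$split_fraction, limb_axis = 3L)
  cut <- sum(apply(regions$proximal, 3, any))
  split_mm <- cut * sp[3]

  rim_windows <- list(
    proximal = c(spec$dbf_edge_margin_mm, split_mm - spec$dbf_split_margin_mm),
    distal = c(split_mm + spec$dbf_split_margin_mm,
               len - if (spec$injection_depot) spec$dbf_depot_margin_mm
                     else spec$dbf_edge_margin_mm))
  dbf_region <- list(proximal = array(FALSE, d), distal = array(FALSE, d))
  for (reg in c("proximal", "distal")) {
    if (!spec$dbf[[reg]]) next
    w <- rim_windows[[reg]]
    if (w[2] <= w[1])
      stop("infeasible phantom spec: no axial room for the ", reg,
           " dermal rim", call. = FALSE)
    m <- array(FALSE, d)
    for (k in which(z_mm >= w[1] & z_mm <= w[2])) {
      inner <- max(radii[k] - spec$dbf_rim_mm, 0)
      m[, , k] <- r2 <= radii[k]^2 & r2 >= inner^2
    }
    dbf_region[[reg]] <- m & masks$subcutaneous
  }
  list(masks = masks, regions = regions, split_mm = split_mm,
       radii = radii, dbf_region = dbf_region)
}

# Fraction of each region's SC voxels a dermal rim would occupy, from the
# geometry alone (used by the cohort generator to respect the HP+rim
# capacity constraint).
rim_sc_fraction <- function(spec) {
  probe <- spec
  probe$dbf <- c(proximal = TRUE, distal = TRUE)
  probe$volume_scale <- 1
  g <- phantom_masks(probe)
  vapply(c("proximal", "distal"), function(r) {
    n_sc <- sum(g$masks$subcutaneous & g$regions[[r]])
    if (n_sc == 0) return(1)
    sum(g$dbf_region[[r]]) / n_sc
  }, numeric(1))
}

#' Generate one synthetic limb phantom
#'
#' Builds the co-registered CT and SPECT volumes described by a
#' [phantom_spec()], together with voxel-level ground truth: compartment
#' masks, HP and DBF masks, per-region DBF/HP patterns, the
#' lymphoscintigraphic findings they imply, the hybrid class, true volumes,
#' and the hotspot exclusion mask for DBF extraction.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `ct` and `spect` (both [image_volume]s on
#'   one grid) and `truth` (list: `masks` ([compartment_masks]), `hp_mask`,
#'   `dbf_mask`, `regions`, `patterns`, `findings`, `stage`, `class`,
#'   `hp_fraction`, `hp_ratio`, `volumes`, `exclusion_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dims
  sp <- spec$spacing
  n <- prod(d)
  nz <- d[3]
  len <- nz * sp[3]

  geom <- phantom_masks(spec)
  masks <- geom$masks
  limb <- masks$limb
  bone <- masks$bone
  muscle <- masks$muscle
  sc <- masks$subcutaneous
  regions <- geom$regions
  split_mm <- geom$split_mm
  radii <- geom$radii
  dbf_region <- geom$dbf_region

  # Feasibility: HP target plus rim occupancy cannot exceed the SC capacity
  # of a region.
  for (reg in c("proximal", "distal")) {
    n_sc <- sum(sc & regions[[reg]])
    if (n_sc == 0) next
    rim_frac <- sum(dbf_region[[reg]]) / n_sc
    if (spec$hp_fraction[[reg]] + rim_frac > 1)
      stop("infeasible phantom spec: hp_fraction (",
           spec$hp_fraction[[reg]], ") plus dermal-rim occupancy (",
           round(rim_frac, 3), ") exceeds the ", reg, " SC capacity",
           call. = FALSE)
  }
  dbf_mask <- dbf_region$proximal | dbf_region$distal

  ## --- CT ---
  hu <- rnorm(n, spec$hu_mean[["air"]], spec$hu_sd[["air"]])
  dim(hu) <- d
  assign_tissue <- function(hu, m, mean, sd) {
    k <- sum(m)
    if (k) hu[m] <- rnorm(k, mean, sd)
    hu
  }
  hu <- assign_tissue(hu, sc, spec$hu_mean[["fat"]], spec$hu_sd[["fat"]])
  hu <- assign_tissue(hu, muscle, spec$hu_mean[["muscle"]],
                      spec$hu_sd[["muscle"]])
  hu <- assign_tissue(hu, bone, spec$hu_mean[["bone"]], spec$hu_sd[["bone"]])

  # HP texture: smoothed random field, thresholded per region at exactly the
  # target SC voxel count, giving connected strands.
  hp_mask <- array(FALSE, d)
  if (any(spec$hp_fraction > 0)) {
    field <- gaussian_blur3(array(rnorm(n), d), spec$hp_texture_mm, sp)
    for (reg in c("proximal", "distal")) {
      frac <- spec$hp_fraction[[reg]]
      if (frac <= 0) next
      in_reg <- which(sc & regions[[reg]])
      k <- round(frac * length(in_reg))
      if (k > 0) {
        pick <- in_reg[order(field[in_reg], decreasing = TRUE)[seq_len(k)]]
        hp_mask[pick] <- TRUE
      }
    }
    n_hp <- sum(hp_mask)
    if (n_hp)
      hu[hp_mask] <- runif(n_hp, spec$hp_window[1], spec$hp_window[2])
  }
  if (spec$ct_noise_sd > 0) hu <- hu + rnorm(n, 0, spec$ct_noise_sd)

  ## --- SPECT ---
  act <- array(0, d)
  act[limb] <- spec$background_activity
  if (any(dbf_mask)) act[dbf_mask] <- spec$dbf_activity
  node_r <- 6
  depot_r <- 7
  duct_r <- 2.5
  offset_frac <- 0.4
  node_prox_c <- c(offset_frac * radii[max(1, round(0.06 * nz))], 0,
                   0.06 * len)
  node_int_c <- c(offset_frac * radii[max(1, round(0.5 * nz))], 0, split_mm)
  depot_c <- c(0.8 * radii[nz], 0, len - 6)
  duct_z <- c(0.10, 0.88) * len
  exclusion <- array(FALSE, d)
  if (spec$duct) {
    act <- paint_duct(act, spec, radii, offset_frac, duct_r, duct_z,
                      spec$duct_activity)
    exclusion <- paint_duct(exclusion, spec, radii, offset_frac,
                            duct_r + spec$hotspot_exclusion_mm, duct_z, TRUE)
  }
  if (spec$node_proximal) {
    act <- paint_sphere(act, spec, node_prox_c, node_r, spec$node_activity)
    exclusion <- paint_sphere(exclusion, spec, node_prox_c,
                              node_r + spec$hotspot_exclusion_mm, TRUE)
  }
  if (spec$node_intermediate) {
    act <- paint_sphere(act, spec, node_int_c, node_r, spec$node_activity)
    exclusion <- paint_sphere(exclusion, spec, node_int_c,
                              node_r + spec$hotspot_exclusion_mm, TRUE)
  }
  if (spec$injection_depot) {
    act <- paint_sphere(act, spec, depot_c, depot_r, spec$depot_activity)
    exclusion <- paint_sphere(exclusion, spec, depot_c,
                              depot_r + spec$depot_exclusion_mm, TRUE)
  }
  sigma <- spec$spect_fwhm_mm / (2 * sqrt(2 * log(2)))
  act_s <- gaussian_blur3(act, sigma, sp)
  counts <- rpois(n, pmax(act_s, 0) * spec$spect_count_scale)
  dim(counts) <- d
  storage.mode(counts) <- "double"

  ## --- truth bookkeeping ---
  hp_present <- spec$hp_fraction >= spec$hp_presence_threshold
  patterns <- list(
    proximal = region_pattern(spec$dbf[["proximal"]],
                              unname(hp_present[["proximal"]])),
    distal = region_pattern(spec$dbf[["distal"]],
                            unname(hp_present[["distal"]])))
  extent <- dbf_flags_to_extent(spec$dbf[["proximal"]], spec$dbf[["distal"]])
  findings <- findings_record(
    dbf_extent = extent,
    proximal_ln_visible = spec$node_proximal,
    intermediate_ln_visible = spec$node_intermediate,
    ducts_visible = spec$duct,
    reading = "planar+SPECT/CT")
  stage <- tls_stage(findings)
  cls <- tryCatch(hybrid_classify(patterns$proximal, patterns$distal,
                                  policy = "strict")$class,
                  error = function(e) NA_integer_)
  vox_cm3 <- voxel_volume_mm3(sp) / 1000
  truth <- list(
    masks = masks,
    hp_mask = hp_mask,
    dbf_mask = dbf_mask,
    dbf_region_masks = dbf_region,
    regions = regions,
    patterns = patterns,
    dbf_extent = extent,
    findings = findings,
    stage = stage$label,
    class = cls,
    hp_fraction = spec$hp_fraction,
    hp_ratio = if (sum(sc)) sum(hp_mask) / sum(sc) else 0,
    volumes = c(limb_cm3 = sum(limb) * vox_cm3,
                sc_cm3 = sum(sc) * vox_cm3,
                hp_cm3 = sum(hp_mask) * vox_cm3,
                dbf_cm3 = sum(dbf_mask) * vox_cm3),
    exclusion_mask = exclusion,
    split_mm = split_mm)

  list(ct = image_volume(hu, sp, "CT", 3L),
       spect = image_volume(counts, sp, "SPECT", 3L),
       truth = truth)
}

# Map per-region DBF flags to the categorical extent.
dbf_flags_to_extent <- function(proximal, distal) {
  if (proximal && distal) "entire"
  else if (proximal) "proximal"
  else if (distal) "distal"
  else "none"
}

# Documented coupling between hybrid class and the distribution of the CT
# volumetric difference (percent) of the affected limb. Class 1 is capped
# below the Grade 1 threshold by construction.
default_severity_coupling <- function() {
  data.frame(class = 1:5,
             diff_min = c(0, 5, 12, 25, 32),
             diff_max = c(8, 15, 28, 45, 55))
}

#' Generate a synthetic patient cohort of paired limb phantoms
#'
#' Draws a hybrid class for each subject from `class_mix`, then builds an
#' affected limb phantom whose per-region DBF/HP patterns realise that
#' class, and an unaffected contralateral limb with no HP and no DBF. The
#' affected limb volume is inflated so the CT volumetric difference grows
#' stochastically with class, following a documented coupling table. Lymph
#' node and duct visibility, lymphedema duration (chronicity) and a
#' simulated planar reading (which occasionally misses DBF or a node, or is
#' contaminated by clothing artefact) are drawn per subject. The full truth
#' label sequence is determined by `(n, class_mix, seed)` alone.
#'
#' @param n number of subjects (>= 1).
#' @param class_mix probabilities (or weights) over hybrid Classes 1-5.
#' @param seed integer seed.
#' @param base_spec template [phantom_spec()]; geometry and noise fields are
#'   taken from it, pattern-related fields are overwritten per subject.
#' @param severity_coupling data.frame with columns `class`, `diff_min`,
#'   `diff_max`: the per-class uniform range of the CT volumetric difference
#'   (percent). Defaults to the built-in coupling table.
#' @param p_planar_dbf_miss probability that the planar reading downgrades
#'   the DBF extent by one step.
#' @param p_planar_ln_miss probability that the planar reading misses a
#'   visible proximal node.
#' @param p_contamination probability of a clothing-contamination artefact:
#'   the planar reading gains a false intermediate node and the subject is
#'   flagged.
#' @return List of `n` subjects; each subject is a list with elements
#'   `study` (list: `ct_affected`, `spect_affected`, `ct_unaffected`,
#'   `exclusion_mask`, `findings_reader`, `findings_planar`, `record`) and
#'   `truth` (the affected-limb phantom truth plus `class`,
#'   `ct_diff_percent`, `severity_grade`, `volumes_unaffected`).
#' @export
generate_cohort <- function(n, class_mix = rep(1 / 5, 5), seed = 1L,
                            base_spec = phantom_spec(),
                            severity_coupling = default_severity_coupling(),
                            p_planar_dbf_miss = 0.15,
                            p_planar_ln_miss = 0.10,
                            p_contamination = 0.05) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (length(class_mix) != 5 || any(class_mix < 0) || sum(class_mix) <= 0)
    stop("`class_mix` must be 5 non-negative weights over Classes 1-5",
         call. = FALSE)
  stopifnot(inherits(base_spec, "phantom_spec"))
  set.seed(seed)

  ## Draw every subject-level label up front so the truth sequence depends
  ## only on (n, class_mix, seed).
  classes <- sample.int(5, n, replace = TRUE, prob = class_mix / sum(class_mix))
  seeds_aff <- sample.int(.Machine$integer.max - 1L, n)
  seeds_unaff <- sample.int(.Machine$integer.max - 1L, n)
  # Probability of visible proximal node (partial obstruction) by class:
  # DBF-dominant low classes drain into nodes; HP-dominant high classes are
  # totally obstructed.
  p_node <- c(0.95, 0.90, 0.60, 0.25, 0.10)[classes]
  node_vis <- runif(n) < p_node
  int_node_vis <- node_vis & runif(n) < 0.5
  duct_vis <- runif(n) < ifelse(node_vis, 0.8, 0.2)
  p_chronic <- c(0.20, 0.30, 0.50, 0.75, 0.90)[classes]
  chronic <- runif(n) < p_chronic
  duration <- ifelse(chronic, runif(n, 12, 140), runif(n, 1, 11.9))
  sc_idx <- match(classes, severity_coupling$class)
  diff_pct <- runif(n, severity_coupling$diff_min[sc_idx],
                    severity_coupling$diff_max[sc_idx])
  patterns <- lapply(classes, draw_class_patterns)
  hp_draw <- matrix(runif(2 * n, 0.15, 0.40), ncol = 2)
  # HP-positive regions that also carry a dermal rim must leave the rim its
  # share of the SC compartment; cap the HP target at the geometric
  # headroom (the rim occupancy is a pure geometry quantity).
  rim_frac <- rim_sc_fraction(base_spec)
  hp_cap_with_rim <- pmax(0.12, 0.95 - rim_frac)
  dbf_miss <- runif(n) < p_planar_dbf_miss
  ln_miss <- runif(n) < p_planar_ln_miss
  contaminated <- runif(n) < p_contamination
  extremity <- sample(c("upper", "lower"), n, replace = TRUE)
  side <- sample(c("left", "right"), n, replace = TRUE)
  age <- round(runif(n, 35, 75))
  planar_miss_pick <- runif(n) # tie-break for entire -> one-region downgrade

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- patterns[[i]]
    hp_frac <- ifelse(pat$hp,
                      ifelse(pat$dbf, pmin(hp_draw[i, ], hp_cap_with_rim),
                             hp_draw[i, ]),
                      0)
    spec_aff <- base_spec
    spec_aff$hp_fraction <- stats::setNames(hp_frac, c("proximal", "distal"))
    spec_aff$dbf <- stats::setNames(pat$dbf, c("proximal", "distal"))
    spec_aff$volume_scale <- 1 + diff_pct[i] / 100
    spec_aff$node_proximal <- node_vis[i]
    spec_aff$node_intermediate <- int_node_vis[i]
    spec_aff$duct <- duct_vis[i]
    spec_aff$seed <- seeds_aff[i]
    spec_unaff <- base_spec
    spec_unaff$hp_fraction <- c(proximal = 0, distal = 0)
    spec_unaff$dbf <- c(proximal = FALSE, distal = FALSE)
    spec_unaff$volume_scale <- 1
    spec_unaff$node_proximal <- TRUE
    spec_unaff$duct <- TRUE
    spec_unaff$seed <- seeds_unaff[i]

    ph_aff <- generate_phantom(spec_aff)
    ph_unaff <- generate_phantom(spec_unaff)

    truth <- ph_aff$truth
    truth$class <- classes[i]
    truth$ct_diff_percent <- diff_pct[i]
    truth$severity_grade <- grade_from_percent(diff_pct[i])
    truth$volumes_unaffected <- ph_unaff$truth$volumes
    truth$chronic <- chronic[i]

    planar <- planar_reading(truth$findings, dbf_miss[i], ln_miss[i],
                             contaminated[i], planar_miss_pick[i])
    record <- data.frame(
      id = sprintf("PH%03d", i), extremity = extremity[i], side = side[i],
      duration_months = round(duration[i], 2),
      contamination_flag = contaminated[i], age = age[i],
      stringsAsFactors = FALSE)
    subjects[[i]] <- list(
      study = list(
        ct_affected = ph_aff$ct, spect_affected = ph_aff$spect,
        ct_unaffected = ph_unaff$ct,
        exclusion_mask = truth$exclusion_mask,
        findings_reader = list(
          proximal_ln_visible = node_vis[i],
          intermediate_ln_visible = int_node_vis[i],
          ducts_visible = duct_vis[i]),
        findings_planar = planar,
        record = record),
      truth = truth)
  }
  subjects
}

# Sample a (proximal, distal) pattern pair realising a hybrid class.
# Returns list(dbf = c(prox, dist), hp = c(prox, dist)).
draw_class_patterns <- function(class) {
  pick <- function(options, prob = NULL) {
    options[[sample.int(length(options), 1, prob = prob)]]
  }
  # each option: list(dbf = ..., hp = ...)
  opt <- switch(class,
    `1` = list(list(dbf = c(FALSE, FALSE), hp = c(FALSE, FALSE))),
    `2` = list(list(dbf = c(TRUE, FALSE), hp = c(FALSE, FALSE)),
               list(dbf = c(FALSE, TRUE), hp = c(FALSE, FALSE)),
               list(dbf = c(TRUE, TRUE), hp = c(FALSE, FALSE))),
    `3` = list(list(dbf = c(TRUE, FALSE), hp = c(TRUE, FALSE)),
               list(dbf = c(FALSE, TRUE), hp = c(FALSE, TRUE)),
               list(dbf = c(TRUE, TRUE), hp = c(TRUE, FALSE)),
               list(dbf = c(TRUE, TRUE), hp = c(FALSE, TRUE)),
               list(dbf = c(TRUE, TRUE), hp = c(TRUE, TRUE))),
    `4` = list(list(dbf = c(TRUE, FALSE), hp = c(TRUE, TRUE)),
               list(dbf = c(FALSE, TRUE), hp = c(TRUE, TRUE))),
    `5` = list(list(dbf = c(FALSE, FALSE), hp = c(TRUE, TRUE))))
  pick(opt)
}

# Simulated planar-only reading derived from the combined-truth findings.
planar_reading <- function(findings, dbf_miss, ln_miss, contaminated,
                           pick) {
  f <- findings
  if (dbf_miss) {
    f$dbf_extent <- switch(f$dbf_extent,
                           entire = if (pick < 0.5) "proximal" else "distal",
                           proximal = "none", distal = "none", none = "none")
  }
  if (ln_miss) f$proximal_ln_visible <- FALSE
  if (contaminated) {
    # clothing artefact misread as an intermediate node on planar imaging
    f$intermediate_ln_visible <- TRUE
    f$contamination_flag <- TRUE
  }
  f$reading <- "planar"
  f
}
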