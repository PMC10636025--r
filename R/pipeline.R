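#' Assemble a full run configuration
#'
#' Bundles every module configuration plus the seed and orchestration
#' policies into one serialisable object. The configuration (and its hash)
#' is echoed into every output bundle for provenance.
#'
#' @param ct a [ct_quant_config()].
#' @param dbf a [dbf_config()].
#' @param rules a TLS rule table, see [default_tls_rules()].
#' @param hp_tau regional HP volume ratio at or above which a region counts
#'   as HP-positive for the hybrid patterns (default 0.05).
#' @param classify_policy fallback policy for [hybrid_classify()] during
#'   cohort runs. The cohort default is `"nearest"` so that one atypical
#'   subject (flagged as imputed) does not abort a batch; set `"strict"`
#'   to error instead.
#' @param split_fraction proximal/distal split plane.
#' @param seed integer seed for every source of randomness in a run.
#' @param output_dir optional directory for masks and CSV outputs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(ct = ct_quant_config(), dbf = dbf_config(),
                       rules = default_tls_rules(), hp_tau = 0.05,
                       classify_policy = c("nearest", "strict"),
                       split_fraction = 0.5, seed = 1L,
                       output_dir = NULL) {
  classify_policy <- match.arg(classify_policy)
  stopifnot(inherits(ct, "ct_quant_config"), inherits(dbf, "dbf_config"),
            hp_tau >= 0, hp_tau <= 1, split_fraction > 0,
            split_fraction < 1)
  validate_tls_rules(rules)
  cfg <- list(ct = ct, dbf = dbf, rules = rules, hp_tau = hp_tau,
              classify_policy = classify_policy,
              split_fraction = split_fraction, seed = as.integer(seed),
              output_dir = output_dir)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# MD5 of the YAML serialisation of a configuration (provenance stamp).
config_hash <- function(cfg) {
  cfg$hash <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys: `ct`, `dbf`, `hp_tau`, `classify_policy`,
#' `split_fraction`, `seed`, `output_dir`; `ct` and `dbf` hold arguments of
#' [ct_quant_config()] and [dbf_config()]. Unspecified values fall back to
#' the package defaults.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file does not exist: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  run_config(
    ct = do.call(ct_quant_config, y$ct %||% list()),
    dbf = do.call(dbf_config, y$dbf %||% list()),
    hp_tau = y$hp_tau %||% 0.05,
    classify_policy = y$classify_policy %||% "nearest",
    split_fraction = y$split_fraction %||% 0.5,
    seed = y$seed %||% 1L,
    output_dir = y$output_dir)
}

# Rethrow any stage error annotated with the stage name and patient id.
with_stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] stage '%s': %s", id, stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full quantification and staging pipeline for one patient
#'
#' Composes the analysis stages in order: limb segmentation of both
#' extremities, compartment segmentation of the affected limb, CT
#' volumetry and severity grading, HP volume ratio (overall and per
#' region), DBF VOI extraction with volume ratio and extent, the per-region
#' DBF/HP patterns and hybrid class, and the TLS stage for the combined
#' reading (and the planar reading when supplied). Any stage error is
#' propagated with the stage name and patient id.
#'
#' @param config a [run_config()].
#' @param study list describing one co-registered study:
#'   `ct_affected`, `spect_affected`, `ct_unaffected` ([image_volume]s),
#'   optional `exclusion_mask` (logical array), optional `findings_reader`
#'   (list with `proximal_ln_visible`, `intermediate_ln_visible`,
#'   `ducts_visible`, optional `normal_drainage` — the human visibility
#'   calls that the combined reading reuses), optional `findings_planar`
#'   (a [findings_record()]) and optional `record` (one-row data.frame
#'   with at least `id`; `contamination_flag` and `duration_months` are
#'   used when present).
#' @return List with the quantification results, masks, findings, stages,
#'   hybrid class and a one-row summary data.frame `row`.
#' @export
run_patient <- function(config, study) {
  stopifnot(inherits(config, "run_config"))
  id <- if (!is.null(study$record)) as.character(study$record$id[1]) else "?"
  ct_aff <- study$ct_affected
  ct_unaff <- study$ct_unaffected
  spect <- study$spect_affected
  stopifnot(inherits(ct_aff, "image_volume"),
            inherits(ct_unaff, "image_volume"),
            inherits(spect, "image_volume"))

  limb_aff <- with_stage("segment_limb(affected)", id,
                         segment_limb(ct_aff, cfg = config$ct))
  limb_unaff <- with_stage("segment_limb(unaffected)", id,
                           segment_limb(ct_unaff, cfg = config$ct))
  comp <- with_stage("segment_compartments", id,
                     segment_compartments(ct_aff, limb_aff, config$ct))
  vol <- with_stage("volumetry", id, volumetric_grade(
    compute_volume(limb_aff, ct_aff$spacing),
    compute_volume(limb_unaff, ct_unaff$spacing)))

  regions <- region_masks(comp$subcutaneous, config$split_fraction,
                          ct_aff$limb_axis)
  hp <- with_stage("hp_ratio", id, hp_ratio(ct_aff, comp$subcutaneous,
                                            config$ct))
  hp_regional <- vapply(regions, function(r) {
    if (!any(r)) return(NA_real_)
    hp_ratio(ct_aff, r, config$ct)$hp_ratio
  }, numeric(1))

  dbf_cfg <- config$dbf
  dbf_cfg$split_fraction <- config$split_fraction
  dbf_mask <- with_stage("extract_dbf", id, extract_dbf(
    spect, seed_points = study$seed_points, sc_mask = comp$subcutaneous,
    cfg = dbf_cfg, exclusion_mask = study$exclusion_mask))
  dbf_r <- with_stage("dbf_ratio", id, dbf_ratio(
    dbf_mask, hp$sc_volume_cm3, spect$spacing))
  ext <- with_stage("dbf_extent", id, dbf_extent(
    dbf_mask, regions, spect$spacing, dbf_cfg))

  hp_present <- !is.na(hp_regional) & hp_regional >= config$hp_tau
  patterns <- list(
    proximal = region_pattern(unname(ext$presence[["proximal"]]),
                              unname(hp_present[["proximal"]])),
    distal = region_pattern(unname(ext$presence[["distal"]]),
                            unname(hp_present[["distal"]])))
  cls <- with_stage("hybrid_classify", id, hybrid_classify(
    patterns$proximal, patterns$distal, policy = config$classify_policy))

  reader <- study$findings_reader %||%
    list(proximal_ln_visible = FALSE, intermediate_ln_visible = FALSE,
         ducts_visible = FALSE)
  findings_combined <- findings_record(
    dbf_extent = ext$extent,
    proximal_ln_visible = isTRUE(reader$proximal_ln_visible),
    intermediate_ln_visible = isTRUE(reader$intermediate_ln_visible),
    ducts_visible = isTRUE(reader$ducts_visible),
    normal_drainage = isTRUE(reader$normal_drainage),
    reading = "planar+SPECT/CT")
  stage_combined <- with_stage("tls_stage", id,
                               tls_stage(findings_combined, config$rules))
  stage_planar <- if (!is.null(study$findings_planar))
    with_stage("tls_stage(planar)", id,
               tls_stage(study$findings_planar, config$rules))

  contamination <- isTRUE(study$record$contamination_flag[1])
  duration <- if (!is.null(study$record$duration_months))
    study$record$duration_months[1] else NA_real_
  row <- data.frame(
    id = id,
    v_affected_cm3 = vol$v_affected_cm3,
    v_unaffected_cm3 = vol$v_unaffected_cm3,
    ct_diff_percent = vol$ct_diff_percent,
    severity_grade = vol$severity_grade,
    hp_ratio = hp$hp_ratio,
    hp_ratio_proximal = hp_regional[["proximal"]],
    hp_ratio_distal = hp_regional[["distal"]],
    dbf_volume_cm3 = dbf_r$dbf_volume_cm3,
    dbf_ratio = dbf_r$dbf_ratio,
    dbf_extent = ext$extent,
    pattern_proximal = patterns$proximal$pattern,
    pattern_distal = patterns$distal$pattern,
    hybrid_class = cls$class,
    class_imputed = cls$imputed,
    stage_combined = stage_combined$label,
    stage_planar = if (is.null(stage_planar)) NA_character_
                   else stage_planar$label,
    contamination_flag = contamination,
    duration_months = duration,
    chronic = if (is.na(duration)) NA else is_chronic(duration),
    stringsAsFactors = FALSE)

  list(row = row, masks = comp, limb_unaffected = limb_unaff,
       volumetry = vol, hp = hp, hp_regional = hp_regional,
       dbf_mask = dbf_mask, dbf = dbf_r, dbf_extent = ext,
       patterns = patterns, hybrid_class = cls,
       findings_combined = findings_combined,
       stage_combined = stage_combined, stage_planar = stage_planar,
       config_hash = config$hash, seed = config$seed)
}

#' Run the pipeline over a cohort and assemble the cohort report
#'
#' Applies [run_patient()] to every subject, then builds the per-patient
#' table, the planar-vs-combined staging comparison, the statistical
#' battery (HP/DBF ratios by severity grade, TLS stage and chronicity;
#' hybrid-class correlations; linear-by-linear trend; the McNemar test of
#' the staging change) and the class distribution. When subjects carry
#' phantom ground truth, a recovery table comparing recovered and true
#' quantities is attached.
#'
#' @param config a [run_config()].
#' @param cohort list of subjects as produced by [generate_cohort()], i.e.
#'   each with a `study` element (and optionally `truth`). If `NULL`, a
#'   phantom cohort is generated with `n`, `class_mix` and the config seed.
#' @param n,class_mix cohort generation parameters used when `cohort` is
#'   `NULL`.
#' @param base_spec template [phantom_spec()] for generated cohorts.
#' @return List: `patients` (data.frame), `staging_comparison`, `stats`,
#'   `class_distribution`, `recovery` (or `NULL`), `config_hash`, `seed`.
#' @export
run_cohort <- function(config, cohort = NULL, n = NULL,
                       class_mix = rep(1 / 5, 5),
                       base_spec = phantom_spec()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(n)) stop("supply `cohort` or `n`", call. = FALSE)
    cohort <- generate_cohort(n, class_mix, seed = config$seed,
                              base_spec = base_spec)
  }
  if (length(cohort) < 2)
    stop("cohort must contain at least 2 patients", call. = FALSE)

  rows <- vector("list", length(cohort))
  recovery <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    res <- run_patient(config, subj$study)
    rows[[i]] <- res$row
    if (!is.null(subj$truth)) {
      tr <- subj$truth
      recovery[[i]] <- data.frame(
        id = res$row$id,
        true_class = tr$class, class = res$row$hybrid_class,
        true_stage = tr$stage, stage = res$row$stage_combined,
        true_extent = tr$dbf_extent, extent = res$row$dbf_extent,
        true_hp_ratio = tr$hp_ratio, hp_ratio = res$row$hp_ratio,
        true_grade = tr$severity_grade, grade = res$row$severity_grade,
        sc_dice = dice(res$masks$subcutaneous,
                       tr$masks$subcutaneous),
        limb_dice = dice(res$masks$limb, tr$masks$limb),
        dbf_dice = dice(res$dbf_mask, tr$dbf_mask),
        stringsAsFactors = FALSE)
    }
  }
  patients <- do.call(rbind, rows)
  recovery <- if (all(vapply(recovery, is.null, logical(1)))) NULL
              else do.call(rbind, recovery)

  staging_comparison <- if (!all(is.na(patients$stage_planar)))
    compare_stagings(patients) else NULL

  stats <- cohort_statistics(patients)
  class_distribution <- table(factor(patients$hybrid_class, levels = 1:5))

  list(patients = patients, staging_comparison = staging_comparison,
       stats = stats, class_distribution = class_distribution,
       recovery = recovery, config_hash = config$hash, seed = config$seed)
}

# The statistical battery over a per-patient results table. Tests that are
# not estimable on the given cohort (e.g. a single severity group) are
# returned as NULL rather than aborting the report.
cohort_statistics <- function(patients) {
  safely <- function(expr) tryCatch(expr, error = function(e) NULL)
  by_groups <- function(values, groups) {
    keep <- !is.na(values) & !is.na(groups)
    split(values[keep], groups[keep])
  }
  grade_groups_hp <- by_groups(patients$hp_ratio, patients$severity_grade)
  stage_groups_hp <- by_groups(patients$hp_ratio, patients$stage_combined)
  grade_groups_dbf <- by_groups(patients$dbf_ratio, patients$severity_grade)
  stage_groups_dbf <- by_groups(patients$dbf_ratio, patients$stage_combined)
  chronic_hp <- by_groups(patients$hp_ratio, patients$chronic)
  chronic_dbf <- by_groups(patients$dbf_ratio, patients$chronic)
  sev01 <- factor(ifelse(patients$severity_grade <= 2, "grade 0-2",
                         "grade 3-4"), levels = c("grade 0-2", "grade 3-4"))
  lbl_tab <- table(factor(patients$hybrid_class, levels = 1:5), sev01)
  mc_tab <- safely(compare_stagings(patients)$table)

  list(
    hp_summary = safely(summarize_numeric(patients$hp_ratio)),
    dbf_summary = safely(summarize_numeric(patients$dbf_ratio)),
    hp_by_grade = safely(kruskal_wallis(grade_groups_hp)),
    hp_by_grade_posthoc = safely(dunn_bonferroni(grade_groups_hp)),
    hp_by_stage = safely(kruskal_wallis(stage_groups_hp)),
    dbf_by_grade = safely(kruskal_wallis(grade_groups_dbf)),
    dbf_by_stage = safely(kruskal_wallis(stage_groups_dbf)),
    hp_by_chronicity = safely(mann_whitney(chronic_hp[["TRUE"]],
                                           chronic_hp[["FALSE"]])),
    dbf_by_chronicity = safely(mann_whitney(chronic_dbf[["TRUE"]],
                                            chronic_dbf[["FALSE"]])),
    class_vs_grade = safely(spearman(patients$hybrid_class,
                                     patients$severity_grade)),
    class_vs_stage = safely(spearman(patients$hybrid_class,
                                     tls_rank(patients$stage_combined))),
    class_severity_trend = safely(linear_by_linear(lbl_tab)),
    staging_mcnemar = safely(if (!is.null(mc_tab)) mcnemar(mc_tab)),
    planar_combined_kappa = safely(
      if (!all(is.na(patients$stage_planar)))
        weighted_kappa(patients$stage_planar, patients$stage_combined,
                       categories = tls_labels())))
}
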