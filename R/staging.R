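## Taiwan Lymphoscintigraphy Staging (TLS) rule engine, the planar-vs-
## combined staging comparison, and the hybrid DBF/HP classification.

DBF_EXTENTS <- c("none", "proximal", "distal", "entire")

#' Ordered TLS stage labels
#'
#' Normal drainage (L-0), partial obstruction (P-1, P-2, P-3) and total
#' obstruction (T-4, T-5, T-6), in increasing ordinal rank (0-6).
#' @return Character vector of the seven labels.
#' @export
tls_labels <- function() c("L-0", "P-1", "P-2", "P-3", "T-4", "T-5", "T-6")

#' Ordinal rank (0-6) of a TLS stage label
#' @param label character vector of stage labels.
#' @return Integer ranks.
#' @export
tls_rank <- function(label) {
  r <- match(label, tls_labels()) - 1L
  if (any(is.na(r) & !is.na(label)))
    stop("unknown TLS label(s): ",
         paste(unique(label[is.na(r) & !is.na(label)]), collapse = ", "),
         call. = FALSE)
  r
}

#' Obstruction group of a TLS stage
#' @param label character vector of stage labels.
#' @return `"normal"` (L-0), `"partial"` (P-1..P-3) or `"total"` (T-4..T-6).
#' @export
tls_group <- function(label) {
  rank <- tls_rank(label)
  c("normal", rep("partial", 3), rep("total", 3))[rank + 1L]
}

#' Construct a lymphoscintigraphic findings record
#'
#' The structured observations the TLS rule engine consumes: the extent of
#' dermal backflow and the visibility of proximal/intermediate lymph nodes
#' and linear lymphatic ducts, plus bookkeeping flags.
#'
#' @param dbf_extent one of `"none"`, `"proximal"`, `"distal"`, `"entire"`.
#' @param proximal_ln_visible,intermediate_ln_visible,ducts_visible logical
#'   visibility calls.
#' @param normal_drainage logical; set when the overall drainage pattern is
#'   read as normal (required, together with node and duct visibility and
#'   absent DBF, for stage L-0).
#' @param contamination_flag logical; marks a reading revised because of a
#'   technical artefact such as clothing contamination.
#' @param reading `"planar"` or `"planar+SPECT/CT"`.
#' @return Object of class `findings_record`.
#' @export
findings_record <- function(dbf_extent,
                            proximal_ln_visible,
                            intermediate_ln_visible = FALSE,
                            ducts_visible = FALSE,
                            normal_drainage = FALSE,
                            contamination_flag = FALSE,
                            reading = c("planar+SPECT/CT", "planar")) {
  dbf_extent <- match.arg(dbf_extent, DBF_EXTENTS)
  reading <- match.arg(reading)
  for (f in list(proximal_ln_visible, intermediate_ln_visible,
                 ducts_visible, normal_drainage, contamination_flag))
    if (!is.logical(f) || length(f) != 1 || is.na(f))
      stop("findings flags must be single non-NA logicals", call. = FALSE)
  structure(list(dbf_extent = dbf_extent,
                 proximal_ln_visible = proximal_ln_visible,
                 intermediate_ln_visible = intermediate_ln_visible,
                 ducts_visible = ducts_visible,
                 normal_drainage = normal_drainage,
                 contamination_flag = contamination_flag,
                 reading = reading),
            class = "findings_record")
}

#' Default TLS rule table
#'
#' A complete decision table over the findings domain (normal-drainage flag
#' x proximal node x intermediate node x ducts x DBF extent). The default
#' encodes: L-0 when drainage is normal with visible nodes and ducts and no
#' DBF; otherwise the partial-obstruction group when a proximal or
#' intermediate node is visualised and the total-obstruction group when
#' neither is; within partial, DBF none/one-region/entire maps to
#' P-1/P-2/P-3; within total, DBF entire/one-region/none maps to
#' T-4/T-5/T-6. The table is data: any replacement table covering the full
#' domain exactly once can be swapped in.
#'
#' @return A `data.frame` with columns `normal_drainage`,
#'   `proximal_ln_visible`, `intermediate_ln_visible`, `ducts_visible`,
#'   `dbf_extent`, `stage`.
#' @export
default_tls_rules <- function() {
  dom <- expand.grid(normal_drainage = c(FALSE, TRUE),
                     proximal_ln_visible = c(FALSE, TRUE),
                     intermediate_ln_visible = c(FALSE, TRUE),
                     ducts_visible = c(FALSE, TRUE),
                     dbf_extent = DBF_EXTENTS,
                     stringsAsFactors = FALSE)
  stage <- character(nrow(dom))
  for (i in seq_len(nrow(dom))) {
    r <- dom[i, ]
    ln <- r$proximal_ln_visible || r$intermediate_ln_visible
    if (r$normal_drainage && r$proximal_ln_visible && r$ducts_visible &&
        r$dbf_extent == "none") {
      stage[i] <- "L-0"
    } else if (ln) {
      stage[i] <- switch(r$dbf_extent, none = "P-1",
                         proximal = "P-2", distal = "P-2", entire = "P-3")
    } else {
      stage[i] <- switch(r$dbf_extent, entire = "T-4",
                         proximal = "T-5", distal = "T-5", none = "T-6")
    }
  }
  dom$stage <- stage
  dom
}

# Check that a rule table covers the findings domain exactly once.
validate_tls_rules <- function(rules) {
  need <- c("normal_drainage", "proximal_ln_visible",
            "intermediate_ln_visible", "ducts_visible", "dbf_extent",
            "stage")
  if (!is.data.frame(rules) || !all(need %in% names(rules)))
    stop("rule table must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  key <- do.call(paste, rules[need[1:5]])
  if (anyDuplicated(key))
    stop("rule table covers some findings combinations more than once",
         call. = FALSE)
  if (nrow(rules) != 2 * 2 * 2 * 2 * length(DBF_EXTENTS))
    stop("rule table is not total over the findings domain (",
         nrow(rules), "/", 64, " rows)", call. = FALSE)
  if (!all(rules$stage %in% tls_labels()))
    stop("rule table assigns unknown stage labels", call. = FALSE)
  invisible(rules)
}

#' Stage a findings record with the TLS rule engine
#'
#' @param findings a [findings_record()].
#' @param rules a complete rule table; defaults to [default_tls_rules()].
#'   Incomplete or ambiguous tables raise a configuration error.
#' @return List with `label`, `rank` (0-6) and `group`
#'   (normal/partial/total).
#' @export
tls_stage <- function(findings, rules = default_tls_rules()) {
  stopifnot(inherits(findings, "findings_record"))
  validate_tls_rules(rules)
  hit <- rules$normal_drainage == findings$normal_drainage &
    rules$proximal_ln_visible == findings$proximal_ln_visible &
    rules$intermediate_ln_visible == findings$intermediate_ln_visible &
    rules$ducts_visible == findings$ducts_visible &
    rules$dbf_extent == findings$dbf_extent
  label <- rules$stage[hit]
  list(label = label, rank = tls_rank(label), group = tls_group(label))
}

#' Compare planar-only and planar+SPECT/CT stage calls over a cohort
#'
#' Builds the stage contingency table (combined reading as rows, planar
#' reading as columns), the number and rate of staging modifications, and
#' the off-diagonal decomposition by obstruction group. Subjects whose
#' reading was revised because of a technical artefact (contamination flag)
#' are excluded from the table and the rate.
#'
#' @param calls data.frame with columns `id`, `stage_planar`,
#'   `stage_combined` and optionally `contamination_flag`.
#' @param labels ordered stage labels spanning both readings; defaults to
#'   the full TLS label set.
#' @return List with `table` (combined rows x planar columns),
#'   `n_total`, `n_excluded_contamination`, `evaluable_n`, `n_modified`,
#'   `modification_rate_percent` and `decomposition` (within_partial,
#'   within_total, partial_to_total, total_to_partial, involving_normal).
#' @export
compare_stagings <- function(calls, labels = tls_labels()) {
  stopifnot(is.data.frame(calls),
            all(c("id", "stage_planar", "stage_combined") %in% names(calls)))
  if (is.null(calls$contamination_flag)) calls$contamination_flag <- FALSE
  miss <- is.na(calls$stage_planar) | is.na(calls$stage_combined)
  if (any(miss))
    stop("subject(s) missing a reading: ",
         paste(calls$id[miss], collapse = ", "), call. = FALSE)
  bad <- !(calls$stage_planar %in% labels) |
    !(calls$stage_combined %in% labels)
  if (any(bad))
    stop("stage labels outside the label set for subject(s): ",
         paste(calls$id[bad], collapse = ", "), call. = FALSE)
  excl <- as.logical(calls$contamination_flag)
  ev <- calls[!excl, , drop = FALSE]
  tab <- table(combined = factor(ev$stage_combined, levels = labels),
               planar = factor(ev$stage_planar, levels = labels))
  n_mod <- sum(tab) - sum(diag(tab))
  gp <- tls_group(ev$stage_planar)
  gc <- tls_group(ev$stage_combined)
  moved <- ev$stage_planar != ev$stage_combined
  decomposition <- c(
    within_partial = sum(moved & gp == "partial" & gc == "partial"),
    within_total = sum(moved & gp == "total" & gc == "total"),
    partial_to_total = sum(moved & gp == "partial" & gc == "total"),
    total_to_partial = sum(moved & gp == "total" & gc == "partial"),
    involving_normal = sum(moved & (gp == "normal" | gc == "normal")))
  list(table = tab,
       n_total = nrow(calls),
       n_excluded_contamination = sum(excl),
       evaluable_n = nrow(ev),
       n_modified = n_mod,
       modification_rate_percent =
         if (nrow(ev)) 100 * n_mod / nrow(ev) else NA_real_,
       decomposition = decomposition)
}

## ---- hybrid DBF/HP classification -------------------------------------

PATTERNS <- c("DBF-/HP-", "DBF+/HP-", "DBF+/HP+", "DBF-/HP+")

#' Per-region DBF/HP pattern
#'
#' The exact product of the two presence flags: DBF-/HP-, DBF+/HP-,
#' DBF+/HP+ or DBF-/HP+.
#'
#' @param dbf_present,hp_present single logicals.
#' @return Object of class `region_pattern` with fields `dbf_present`,
#'   `hp_present`, `pattern`.
#' @export
region_pattern <- function(dbf_present, hp_present) {
  stopifnot(is.logical(dbf_present), is.logical(hp_present),
            length(dbf_present) == 1, length(hp_present) == 1,
            !is.na(dbf_present), !is.na(hp_present))
  pattern <- paste0("DBF", if (dbf_present) "+" else "-",
                    "/HP", if (hp_present) "+" else "-")
  structure(list(dbf_present = dbf_present, hp_present = hp_present,
                 pattern = pattern),
            class = "region_pattern")
}

as_pattern_string <- function(x) {
  if (inherits(x, "region_pattern")) return(x$pattern)
  if (is.character(x) && length(x) == 1 && x %in% PATTERNS) return(x)
  stop("expected a region_pattern or one of: ",
       paste(PATTERNS, collapse = ", "), call. = FALSE)
}

# Number of differing presence flags between two patterns (0..2).
pattern_hamming <- function(a, b) {
  fa <- c(substr(a, 4, 4), substr(a, 8, 8))
  fb <- c(substr(b, 4, 4), substr(b, 8, 8))
  sum(fa != fb)
}

# Literal class rules, applied in order 1..5 to the (proximal, distal)
# pattern multiset. Returns NA when no rule matches.
classify_pair <- function(p, q) {
  pats <- c(p, q)
  has <- function(x) x %in% pats
  if (all(pats == "DBF-/HP-")) return(1L)
  if (has("DBF+/HP-") && !has("DBF+/HP+") && !has("DBF-/HP+")) return(2L)
  if (has("DBF+/HP+") && !has("DBF-/HP+")) return(3L)
  if (has("DBF+/HP+") && has("DBF-/HP+")) return(4L)
  if (all(pats == "DBF-/HP+")) return(5L)
  NA_integer_
}

#' Hybrid SPECT/CT class from the two region patterns
#'
#' Applies the five class rules in order: Class 1 when neither region shows
#' DBF or HP; Class 2 when DBF without HP is present and no region shows
#' DBF+/HP+ or DBF-/HP+; Class 3 when DBF+/HP+ is present without any
#' DBF-/HP+; Class 4 when DBF+/HP+ and DBF-/HP+ coexist; Class 5 when HP
#' without DBF fills the entire extremity. Four of the sixteen ordered
#' pattern pairs are covered by no rule; under the default `strict` policy
#' these raise an error naming the pair, while `nearest` assigns the class
#' whose covered pattern pairs are closest in presence-flag Hamming
#' distance (ties broken toward the lower class) and tags the result as
#' imputed.
#'
#' @param proximal,distal [region_pattern()] objects or pattern strings.
#' @param policy `"strict"` or `"nearest"`.
#' @return List with `class` (1-5) and `imputed` (logical).
#' @export
hybrid_classify <- function(proximal, distal,
                            policy = c("strict", "nearest")) {
  policy <- match.arg(policy)
  p <- as_pattern_string(proximal)
  q <- as_pattern_string(distal)
  cls <- classify_pair(p, q)
  if (!is.na(cls)) return(list(class = cls, imputed = FALSE))
  if (policy == "strict")
    stop("pattern pair (", p, ", ", q, ") matches no hybrid class; ",
         "use policy = 'nearest' to impute", call. = FALSE)
  covered <- expand.grid(p = PATTERNS, q = PATTERNS,
                         stringsAsFactors = FALSE)
  covered$class <- mapply(classify_pair, covered$p, covered$q)
  covered <- covered[!is.na(covered$class), ]
  d <- mapply(function(cp, cq) pattern_hamming(p, cp) + pattern_hamming(q, cq),
              covered$p, covered$q)
  best <- min(d)
  cls <- min(covered$class[d == best])
  list(class = as.integer(cls), imputed = TRUE)
}

#' Full decision table of the hybrid classifier
#'
#' Enumerates all sixteen ordered (proximal, distal) pattern pairs and the
#' class each receives, marking strict-unclassifiable pairs.
#'
#' @param policy passed to [hybrid_classify()] for the imputed column.
#' @return data.frame with columns `proximal`, `distal`, `class` (NA under
#'   strict for uncovered pairs), `unclassifiable`, `imputed`.
#' @export
hybrid_decision_table <- function(policy = c("strict", "nearest")) {
  policy <- match.arg(policy)
  grid <- expand.grid(proximal = PATTERNS, distal = PATTERNS,
                      stringsAsFactors = FALSE)
  grid$class <- NA_integer_
  grid$unclassifiable <- FALSE
  grid$imputed <- FALSE
  for (i in seq_len(nrow(grid))) {
    cls <- classify_pair(grid$proximal[i], grid$distal[i])
    if (is.na(cls)) {
      grid$unclassifiable[i] <- TRUE
      if (policy == "nearest") {
        r <- hybrid_classify(grid$proximal[i], grid$distal[i], "nearest")
        grid$class[i] <- r$class
        grid$imputed[i] <- TRUE
      }
    } else {
      grid$class[i] <- cls
    }
  }
  grid
}
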