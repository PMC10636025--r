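# lymphspect

Quantification and staging of secondary extremity lymphedema from hybrid
SPECT/CT lymphoscintigraphy.

Planar lymphoscintigraphy is the workhorse for grading lymphatic
obstruction, but it is a projection image: dermal backflow (DBF) can hide
behind overlying activity, faint lymph-node uptake can be missed, and skin
or clothing contamination can masquerade as a node. Adding a SPECT/CT
acquisition contributes two quantifiable signals — **DBF** on SPECT
(retrograde tracer in dermal lymphatics, the functional sign of
obstruction) and the **honeycomb pattern (HP)** on CT (fibrotic strands in
the subcutaneous fat, the structural sign of chronic disease). This
package is for imaging scientists and nuclear-medicine researchers who
want that analysis chain scripted, seeded and testable end to end.

## What it computes

For one patient (affected + unaffected limb, co-registered CT/SPECT):

* compartment segmentation by region growing and Hounsfield windowing,
  with the subcutaneous (SC) compartment defined by subtraction,
  `SC = limb − muscle − bone` (enforced as an identity);
* **HP volume ratio** `V_HP / V_SC`, where HP = SC voxels in [−60, 10] HU;
* **CT volumetric difference**
  `100 × (V_aff − V_unaff) / V_unaff`, graded 0–4 in half-open 10% bands;
* **DBF volume ratio** `V_DBF / V_SC` from a 3-D iso-contour VOI (10% of
  the seed-connected maximum, hotspot exclusions, 1 cm³ minimum volume),
  with a per-region extent call (none/proximal/distal/entire);
* the **Taiwan Lymphoscintigraphy Staging** (L-0, P-1…P-3, T-4…T-6) from a
  swappable rule table over DBF extent and node/duct visibility;
* the **hybrid SPECT/CT class** (1–5) from the per-region DBF/HP pattern
  pair, with a strict-by-default policy for the four pattern pairs the
  class definitions do not cover.

For a cohort: the planar-vs-combined staging comparison (contingency
table, modification rate, off-diagonal decomposition, contamination
exclusions) and the nonparametric battery (McNemar–Bowker, Kruskal–Wallis
with Dunn–Bonferroni post hoc, Mann–Whitney, Spearman, linear-by-linear
trend, weighted kappa, Shapiro–Wilk-gated summaries).

Because studies of this kind do not deposit raw images, the package
includes a seeded limb-phantom generator (`phantom_spec`,
`generate_phantom`, `generate_cohort`) producing paired CT/SPECT volumes
with voxel-level ground truth; the test suite validates the whole pipeline
by parameter recovery against that truth.

## Worked example

```r
library(lymphspect)

# An affected limb: 18% volume excess, distal dermal backflow with
# honeycomb change (HP target 0.25 distally), nodes still visible.
spec <- phantom_spec(hp_fraction = c(proximal = 0, distal = 0.25),
                     dbf = c(proximal = FALSE, distal = TRUE),
                     volume_scale = 1.18, seed = 42)
ph <- generate_phantom(spec)

spec_un <- spec
spec_un$hp_fraction <- c(proximal = 0, distal = 0)
spec_un$dbf <- c(proximal = FALSE, distal = FALSE)
spec_un$volume_scale <- 1
spec_un$seed <- 43L
un <- generate_phantom(spec_un)

study <- list(ct_affected = ph$ct, spect_affected = ph$spect,
              ct_unaffected = un$ct,
              exclusion_mask = ph$truth$exclusion_mask,
              findings_reader = list(proximal_ln_visible = TRUE,
                                     intermediate_ln_visible = FALSE,
                                     ducts_visible = TRUE),
              record = data.frame(id = "EX01", contamination_flag = FALSE,
                                  duration_months = 30))
res <- run_patient(run_config(seed = 42), study)
t(res$row[, c("ct_diff_percent", "severity_grade", "hp_ratio",
              "hp_ratio_distal", "dbf_ratio", "dbf_extent",
              "pattern_proximal", "pattern_distal", "hybrid_class",
              "stage_combined")])
#> ct_diff_percent   "17.97506"
#> severity_grade    "1"
#> hp_ratio          "0.1093515"
#> hp_ratio_distal   "0.2407911"
#> dbf_ratio         "0.281842"
#> dbf_extent        "distal"
#> pattern_proximal  "DBF-/HP-"
#> pattern_distal    "DBF+/HP+"
#> hybrid_class      "3"
#> stage_combined    "P-2"
```

Reading the output: the affected limb carries 18% excess volume (severity
Grade 1, the [10, 20) band). Distally, 24% of the subcutaneous compartment
falls in the honeycomb window and a dermal-backflow VOI of 28% of the SC
volume was grown, so the distal pattern is DBF+/HP+ while the proximal
limb is clean — hybrid Class 3. With nodes visible and single-region DBF,
the TLS stage is P-2 (partial obstruction).

The staging-comparison engine reproduces a published-style table directly
from stage calls:

```r
calls <- read.csv(system.file("extdata", "tls_staging_example.csv",
                              package = "lymphspect"))
cmp <- compare_stagings(calls)
round(cmp$modification_rate_percent, 1)   # 15.4  (6 of 39 evaluable)
cmp$decomposition
#> within_partial   within_total   partial_to_total   total_to_partial
#>              2              0                  0                  4
#> involving_normal
#>                0
```

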