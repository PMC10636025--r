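---
title: "Quantifying and staging extremity lymphedema from SPECT/CT lymphoscintigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and staging extremity lymphedema from SPECT/CT lymphoscintigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphspect)
```

## The clinical problem

Secondary extremity lymphedema — most often a sequela of cancer treatment —
is staged functionally with lymphoscintigraphy: an intradermal Tc-99m
tracer depot is injected in the webspaces of both hands or feet, and the
drainage pattern is read from planar scintigrams. Planar imaging has poor
spatial resolution, so two complementary hybrid-imaging signals can be
added from a SPECT/CT acquisition:

* **Dermal backflow (DBF)**, on SPECT: retrograde tracer accumulation in
  dermal lymphatic capillaries, the functional hallmark of lymphatic
  obstruction. It appears early, grows with severity, and can vanish again
  when the lymphatics finally fail.
* **Honeycomb pattern (HP)**, on CT: trabeculated fibrotic/fluid strands in
  the subcutaneous (SC) fat, a structural sign of chronic disease that
  accumulates monotonically.

`lymphspect` implements the full quantitative chain around these two
signals: compartment segmentation, the HP and DBF volume ratios, CT
volumetric severity grading, the Taiwan Lymphoscintigraphy Staging (TLS)
rule engine with a planar-vs-combined staging comparison, a five-class
hybrid DBF/HP classification, and the nonparametric statistical battery
used for cohort analyses. Because no patient images are publicly deposited
for this kind of study, the package ships a synthetic limb-phantom
generator with voxel-level ground truth; every recovery claim made by the
test suite is a claim about those phantoms, as discussed at the end.

## Quantification model

**Compartments.** The limb is segmented from CT by seeded region growing
over the connected set of voxels above an air/soft-tissue cut (default
−300 HU). Bone is thresholded at ≥ 150 HU and muscle in the [20, 100] HU
window, both cleaned by one iteration of 6-connected morphological closing;
muscle keeps only its largest connected component so that stray SC voxels
in the window cannot join it. The SC compartment is defined *by
subtraction*: `SC = limb & !(bone | muscle)`. The `compartment_masks`
container enforces this identity — a mask set violating it is rejected at
construction, so the identity is structural rather than conventional.

**HP volume ratio.** HP is operationalised as SC voxels inside the
[−60, 10] HU window, inclusive at both bounds (the bound semantics are not
standardised, so inclusivity is declared and boundary-tested). The HP
volume ratio is HP volume over SC volume of the affected limb. The
unaffected limb's HP ratio can be computed but is auxiliary; all reported
ratios reference the affected extremity.

**CT volumetric severity.** The volumetric difference is
`100 × (V_affected − V_unaffected) / V_unaffected`, graded with half-open
bands: Grade 0 below 10%, Grade 1 in [10, 20), Grade 2 in [20, 30), Grade
3 in [30, 40), Grade 4 at 40% and above — each percentage has exactly one
grade, and 10/20/30/40 map upward. Negative differences clamp to Grade 0
with a warning.

**DBF volume ratio.** The DBF volume of interest is grown by 3-D
iso-contouring: from each seed, the connected voxels whose activity reaches
`iso_fraction` (default 0.10) of the seed-connected maximum; the maximum is
refined iteratively until stable. The result is intersected with the SC
compartment (dermal backflow is a subcutis phenomenon), injection-depot and
nodal/duct hotspots are removed via exclusion masks, and components below
`min_volume_cm3` (default 1 cm³) are dropped to suppress noise speckle.
Auto-seeding takes the brightest SC voxel per limb region outside the
exclusions; a seed is accepted only if it clears
`max(5 × background, 0.05 × global maximum)`, where background is the
median non-zero activity of deep (non-SC) tissue. Deep tissue is used
deliberately: with entire-limb DBF the SC compartment itself is mostly
backflow, so any SC-based background estimate would be contaminated by the
very signal being sought. The global-maximum term keeps smoothed hotspot
tails from seeding spurious VOIs. DBF presence per region requires at
least `min_volume_cm3` of VOI inside the region; the extent is `none`,
`proximal`, `distal` or `entire`.

## Staging and classification

**TLS rule engine.** The seven ordinal stages (L-0; partial P-1–P-3; total
T-4–T-6) are produced by a *data* rule table covering the full findings
domain (normal-drainage flag × proximal node × intermediate node × ducts ×
DBF extent = 64 combinations) exactly once; incomplete or ambiguous tables
are a configuration error at load time. The default table encodes: partial
obstruction when a proximal or intermediate node is visualised, total
otherwise; within partial, DBF none → P-1, one region → P-2, entire → P-3;
within total, entire → T-4, one region → T-5, none → T-6; and L-0 when the
drainage is explicitly read as normal with visible nodes and ducts and no
DBF. Two genuinely open points are resolved as follows and isolated in the
table: (i) L-0 requires duct visibility *and* the normal-drainage call —
the stage systems in circulation do not pin this down, and requiring both
avoids mislabelling a P-1 as normal; (ii) the `findings_record` carries an
explicit `normal_drainage` flag for the same reason.

**Staging comparison.** `compare_stagings` builds the contingency table
with the combined (planar+SPECT/CT) reading as rows and the planar-only
reading as columns, excludes subjects whose reading was corrupted by
technical artefact (clothing contamination), and reports the modification
count, the rate over evaluable subjects, and the off-diagonal decomposition
(within-partial, within-total, partial→total, total→partial).

**Hybrid classes.** Each region (proximal/distal, split at a configurable
fractional plane, default 0.5 — elbow/knee positions are not standardised,
so the split is a parameter) gets one of four patterns from the DBF and HP
presence flags; HP presence uses a regional HP-ratio threshold `hp_tau`
(default 0.05, configurable — published work reports presence/absence
without a numeric cut). The five classes are applied in order: Class 1
(no DBF, no HP anywhere), Class 2 (DBF+/HP− without any DBF+/HP+ or
DBF−/HP+), Class 3 (DBF+/HP+ without any DBF−/HP+), Class 4 (DBF+/HP+ and
DBF−/HP+ coexisting), Class 5 (DBF−/HP+ in the entire limb). Exactly 4 of
the 16 ordered pattern pairs — those with a DBF−/HP+ region next to a
DBF−/HP− or DBF+/HP− region — are covered by no class. The default policy
is `strict` (an explicit error naming the pair: silently guessing would
fabricate data), with an opt-in `nearest` policy that assigns the class
with the smallest presence-flag Hamming distance over its covered pairs,
ties broken toward the lower class, and tags the output as imputed.
`run_cohort` uses `nearest` by default so one atypical subject cannot
abort a batch; imputations remain flagged per patient.

## Statistical battery

Group comparisons and correlations delegate to the standard R machinery
(`kruskal.test`, `wilcox.test`, `cor.test`, `shapiro.test`) with explicit,
never silent, exact/asymptotic switches. Three pieces are computed in the
package. The McNemar–Bowker statistic skips symmetric pairs with zero
total count and reduces the degrees of freedom accordingly (the stock
implementation returns NaN there). Dunn's post-hoc z-tests use mid-ranks
with the usual tie correction and Bonferroni adjustment (adjusted p is
never below raw and caps at 1). The linear-by-linear association statistic
is `M² = (N−1) r²` with integer scores by default. Weighted kappa offers
linear (default) and quadratic weights — the weighting scheme is always
echoed in the output, since published reports often omit it — and maps the
point estimate to the conventional agreement bands (≤ 0.20 poor, ≤ 0.40
fair, ≤ 0.60 moderate, ≤ 0.80 substantial, above that almost perfect).
Numeric summaries compute both mean/SD and median/IQR and use a
Shapiro–Wilk gate at α = 0.05 only to choose the display form.

## The phantom: what it emulates, and what it does not

Each limb is a tapered cylinder (proximal radius 40 mm, distal taper 0.8,
192 mm axis) with concentric bone (15% of the local radius), muscle (to
65%) and SC compartments, on a 96³ grid with 2 mm voxels by default.
Hounsfield distributions are conventional radiology values (bone
700 ± 100, muscle 50 ± 10, fat −100 ± 15, air −1000 ± 20 HU), plus
additive CT noise (default SD 3 HU). HP texture is a Gaussian random field
smoothed at 4 mm and thresholded per region at exactly the target SC voxel
count — giving connected strand-like structures rather than i.i.d. voxel
salt, because windowing and region growing behave differently on connected
structures. SPECT activity is painted (soft-tissue background 0.05, dermal
rim 30, nodes 40, duct 5, injection depot 60 arbitrary units), blurred by
an isotropic Gaussian PSF (FWHM 12 mm, a typical gamma-camera resolution),
scaled to an expected 20 counts per activity unit and Poisson-sampled.

The dermal rim is 12 mm thick, measured inward from the skin — dermal plus
immediate subdermal backflow, which is what a 12 mm-PSF system can resolve
— and stands off axially from the split plane (12 mm), the proximal end
(8 mm) and the injection depot (32 mm), since blur would otherwise smear
single-region backflow across the split or merge it with the depot. The
ground-truth exclusion mask dilates the nodal/duct hotspots by 12 mm and
the depot by 18 mm: just beyond the radius at which their smoothed tails
can exceed the 10% iso-contour of a local maximum. A rim occupies 0.55–0.7
of a region's SC voxels by geometry, so the feasibility guard (HP target +
rim occupancy ≤ SC capacity) binds for regions carrying both signals; the
cohort generator therefore draws HP targets in [0.15, 0.40] and caps them
at the geometric headroom (0.95 − rim fraction, floor 0.12) for
DBF-coexistent regions.

The cohort generator draws a hybrid class per subject, realises it as a
pattern pair, and couples the remaining variables to class through
documented configuration: the CT volumetric difference is uniform per
class (Class 1: 0–8%, 2: 5–15%, 3: 12–28%, 4: 25–45%, 5: 32–55% — Class 1
stays below the Grade 1 threshold by construction), node visibility
probability falls with class (0.95 down to 0.10), and chronicity
probability rises (0.20 up to 0.90). A simulated planar reading downgrades
the DBF extent with probability 0.15, misses a proximal node with 0.10,
and suffers clothing contamination (a false intermediate node, flagged)
with 0.05. All subject-level draws happen before any volume is generated,
so the truth-label sequence depends only on `(n, class_mix, seed)`.

What the phantom does **not** emulate: attenuation, scatter and collimator
physics beyond a Gaussian PSF; partial-volume CT at tissue boundaries
(compartments are voxel-exact); skin thickening, epifascial fluid lakes
and other CT signs of lymphedema besides HP; anatomically realistic limb
shapes, joints or vasculature; and multi-timepoint transport kinetics.
Passing recovery tests therefore demonstrates that the pipeline correctly
inverts its own generative model at realistic noise — a necessary
condition and a regression harness, not clinical validation on patient
images.

## Numerical choices and degenerate inputs

Voxel connectivity is 6 (faces) throughout by default. Region growing and
component labeling run in compiled code (breadth-first, first-encounter
label order). The HP window and grade bands are closed/half-open exactly
as stated above and swept at their boundaries in the tests. Empty SC masks
make the HP ratio an explicit error, never a silent zero; an unaffected
volume of zero is an error; a seed in air is an error; manual DBF seeds
below the background gate are an error, while auto-seeded regions that
fail the gate simply report no DBF. All-tied samples short-circuit the
Kruskal–Wallis statistic to 0, and constant samples skip the Shapiro–Wilk
gate with a flag.

## Validation problem sizes

The test suite exercises the full pipeline on 48³ phantoms with 4 mm
voxels (same anatomy, coarser grid) for speed, and the end-to-end
validation uses a 40-subject cohort at the default 96³/2 mm resolution —
about the size of a single-centre retrospective series, and enough to
exercise every class and extent. On those 40 phantoms the pipeline
recovers the HP volume ratio within ±0.03 of truth, the DBF extent in at
least 95% of subjects, the SC compartment at Dice ≥ 0.95, and the hybrid
class at Spearman ≥ 0.8 against truth; `scripts/acceptance.R` recomputes
these quantities from scratch at any seed.

## Known limitations

* Iso-contour equivalence with commercial VOI tools cannot be asserted;
  only internal-oracle equivalence is tested, and the iso fraction is
  reported alongside results.
* The TLS rule table is a reconstruction from published stage descriptors;
  any divergence from the originating clinical definition is isolated to
  one editable table.
* The nearest-class fallback is a flagged imputation, not a clinical
  judgement.
* With no injection depot and no uptake anywhere, the global-maximum term
  of the seed gate degenerates and background Poisson speckle could seed a
  VOI; a lymphoscintigraphy study without a visible depot is itself a
  failed acquisition, so this is not guarded beyond the minimum-volume
  filter.
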