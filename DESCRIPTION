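Package: lymphspect
Title: Quantification and Staging of Extremity Lymphedema from SPECT/CT
    Lymphoscintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of paired SPECT/CT lymphoscintigraphy
    studies of secondary extremity lymphedema. Segments limb, bone, muscle
    and subcutaneous compartments from CT by region growing and Hounsfield
    windowing; measures the honeycomb-pattern (HP) volume ratio in the
    subcutaneous compartment and the dermal-backflow (DBF) volume ratio
    from SPECT iso-contour volumes of interest; grades clinical severity
    from CT limb volumetry; applies the Taiwan Lymphoscintigraphy Staging
    rule engine and a five-class hybrid DBF/HP classification; and runs the
    accompanying nonparametric cohort statistics (McNemar-Bowker,
    Kruskal-Wallis with Dunn-Bonferroni post hoc, Mann-Whitney, Spearman,
    linear-by-linear association, weighted kappa). A synthetic limb-phantom
    generator with voxel-level ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
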