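Package: osseoquant
Title: Quantification of Scaffold Osseointegration from Histology, CT and
    Nanoindentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification stack for cranioplasty scaffold studies:
    HSV color-gate histomorphometry of stained resin sections with
    kernel-defined scaffold borders and regional percent bony ingrowth;
    Oliver-Pharr analysis of nanoindentation load-displacement curves
    (reduced modulus, hardness, bone elastic modulus) with per-specimen
    aggregation; clock-face bridging scores of the implant-bone interface
    and inter-rater intraclass correlation; Hounsfield-threshold CT
    volumetrics; and the small-sample statistical battery (Shapiro-Wilk,
    one-way ANOVA with Tukey HSD, pooled t tests with Bonferroni
    correction, Mann-Whitney, Kruskal-Wallis with Dunn post hoc) together
    with a driver that reproduces the study's summary tables from
    per-subject fixtures. A synthetic-data module generates micrographs,
    indentation curves, interface rings, Hounsfield volumes and cohort
    tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
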