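Package: mechphen
Title: Single-Cell Mechanophenotyping Assay Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for four single-cell mechanophenotyping assays:
    traction force microscopy on elastic micropillar arrays, magnetic-tweezers
    pulsatile mechanosensing, AFM nanoindentation with spherical-probe Hertz
    fitting, and basement-membrane transmigration quantified from two-channel
    confocal z-stacks. Includes a ground-truthed synthetic-data generator for
    every assay, cohort-level simulation from published condition summaries,
    and the group-comparison statistics scheme used in cell mechanics studies
    (normality gating, Welch/Brown-Forsythe corrections, Kruskal-Wallis with
    Dunn post-hoc, paired Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    withr,
    car,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
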