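Package: hcmorph
Title: Morphometry of Nuclear Position and Envelope Recruitment in Cochlear Hair Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nuclear mislocalization phenotypes in cochlear outer
    hair cells from multi-channel fluorescence stacks and landmark
    annotations. Computes the relative nuclear position along a smooth cell
    axis fitted through apical, nuclear and basal landmarks; a perinuclear
    band recruitment index for nuclear-envelope reporters built on an
    anisotropic Euclidean distance transform; lateral gap statistics between
    submembrane cisternae segments; hair-cell counts per cochlear region;
    and the cohort comparison statistics used for such phenotypes
    (Kruskal-Wallis with Dunn's post hoc, ANOVA with Tukey HSD, Welch t
    tests with two-stage step-up false-discovery control, Mann-Whitney,
    normality pre-tests). Includes a ground-truthed synthetic image and
    cohort generator so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    nortest,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
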