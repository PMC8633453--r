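Package: pcfdc
Title: Lesion Network Mapping with Principal-Component Refined Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lesion network mapping in a normative functional
    connectome: embeds binary stroke lesions as seeds in resting-state BOLD
    runs and estimates indirect functional disconnection. Implements the
    whole-lesion functional disconnection (FDC) baseline and its
    principal-component refinement (PC-FDC), which builds a within-lesion
    connectivity-strength matrix across normative subjects, extracts the
    first principal component, and thresholds its back-projected
    coefficients to retain the coherent (mostly grey-matter) lesion voxels
    before seeding. Includes Fisher-z r-maps and sign-flip permutation
    t-maps with max-statistic family-wise error control, winner-take-all
    network atlas assignment with a network confidence index, map-comparison
    statistics (CDF cut-offs, dice, Wilcoxon signed-rank, Friedman,
    voxelwise permutation tests with a lesion-size covariate), a ridge
    regression behaviour-prediction framework with nested leave-one-out
    cross-validation and permutation significance, and a synthetic-cohort
    generator so every stage is testable without any neuroimaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
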