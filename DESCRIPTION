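Package: checkfish
Title: Quantification of Stereotypical Checking Behavior and Two-Epoch
    Immediate-Early-Gene Ensemble Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying drug-induced stereotypical checking in
    rodent open-field experiments and for analysing catFISH (cellular
    compartment analysis of temporal activity by fluorescence in situ
    hybridization) data. Converts head trajectories from an object-enriched
    arena into zone-visit counts, per-animal A-F zone rankings, locomotor
    sensitization curves and standardized session comparisons; classifies
    segmented nuclei into negative, Homer1a-positive, Arc-positive and
    double-positive classes using per-slide weakest-exemplar thresholds,
    mid-Z-stack selection and glia exclusion; computes per-region class
    proportions, the two-epoch ensemble similarity score, percent-reduction
    contrasts and the associated factorial repeated-measures analyses.
    Seeded synthetic generators for trajectories and two-epoch nuclei
    populations with known ground truth make every stage testable without
    raw video or microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
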