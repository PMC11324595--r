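Package: bwasr
Title: Brain-Wide Association Study of Voxel-Wise Functional Connectivity
Version: 0.1.0
Authors@R: person("BWAS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for brain-wide association studies (BWAS) of
    resting-state fMRI functional connectivity. Computes all-pairs voxel
    Pearson correlations with Fisher z-transformation, covariate-adjusted
    link-level group tests under Bonferroni family-wise error control, the
    per-voxel Measure-of-Association (MA) statistic with cluster extraction,
    atlas-anchored region-of-interest (ROI) derivation, ROI-wise connectivity
    group comparisons with Benjamini-Hochberg false discovery rate control,
    bootstrap brain-behavior correlation, and time-domain half-split
    reliability. Includes a synthetic two-group cohort generator with known
    ground truth, a minimal NIfTI-1 reader/writer, and preprocessing
    utilities (nuisance regression, band-pass filtering, Gaussian smoothing,
    framewise displacement).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
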