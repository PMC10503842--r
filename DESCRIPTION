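Package: csfmotion
Title: Cerebrospinal Fluid Motion Mapping and Choroid Plexus Perfusion
    from Diffusion and Arterial Spin Labeling MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebrospinal-fluid (neurofluid) motion from
    multi-b-value diffusion-weighted MRI by voxelwise exponential
    decay-rate mapping, and choroid plexus perfusion from
    pseudo-continuous arterial spin labeling via surround subtraction,
    M0 normalization and single-compartment kinetic-model inversion.
    Includes a digital phantom and synthetic-cohort generator with
    Rician noise and rank-correlation structure, plus the cohort-level
    rank-based statistics (Wilcoxon rank-sum, chi-squared, Spearman,
    simple linear regressions) used to compare Parkinson's disease and
    healthy groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    optparse
Config/testthat/edition: 3
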