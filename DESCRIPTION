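Package: ferroscale
Title: Iron Speciation Imaging and Temporal-Rescaling Survival Analysis for
    Aging Nematodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for studying ferroptosis-linked aging in
    Caenorhabditis elegans: estimation of the in vivo ferrous iron fraction
    from fluorescence-detected XANES image stacks (energy-axis calibration,
    calcium cross-correlation alignment, edge-jump normalization, pre-edge
    Gaussian centroid and first-derivative speciation), per-animal iron
    quantification from X-ray fluorescence microscopy elemental maps
    (Compton-scatter segmentation, Currie critical-level background
    correction, foil calibration), and a survival-analysis suite testing
    whether lifespan interventions act by temporal rescaling (Buckley-James
    accelerated failure time fits, a censoring-aware permutation
    Kolmogorov-Smirnov residual test, Weibull-Gamma frailty models with
    departure terms, likelihood-ratio model selection, inverse-variance
    meta-analysis, hazard-rate curves), plus the dose-response and
    cross-sectional cohort statistics that accompany such studies. A
    synthetic-data module generates lifespan cohorts, XANES stacks, elemental
    scenes and dose-response tables with known ground truth so the whole
    pipeline is testable without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
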