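Package: wallpulse
Title: Uncertainty-Aware Quantification of Intracranial Aneurysm Wall
    Motion from ECG-Gated 4D-CTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cardiac-cycle-resolved (ECG-gated 4D-CTA)
    segmentations of unruptured saccular intracranial aneurysms. Provides
    seeded 4D sphere-on-vessel phantom generators with known ground truth;
    segmentation post-processing (thresholding, box smoothing, linear
    resampling, isosurface extraction); thinning-based centerline and
    key-point extraction with automatic neck-plane construction and sac
    isolation; per-vertex wall-displacement mapping; direct geometric
    parameters and ratio-based morphology indices (AR, SR, UI, NSI, BF, CP);
    detection of global volumetric pulsation against a robust MAD-based
    noise floor, spatial wall pulsation against amplitude/area/fraction
    thresholds, and longitudinal size change against phase-wise measurement
    variability; first-harmonic signal decomposition with residual-MAD
    deformability gated by a Bland-Altman minimum detectable change; and the
    exact 2x2 contingency statistics (two-sided Fisher test, conditional-MLE
    odds ratio with exact confidence interval, Newcombe risk difference,
    Hedges' g, Spearman and Mann-Whitney tests) used to relate baseline
    pulsation to longitudinal aneurysm size change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
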