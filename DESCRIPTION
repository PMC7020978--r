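Package: dose4d
Title: Phase-Resolved Dose Accumulation and NTCP Analysis for Liver SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing internal-target-volume (ITV) based
    three-dimensional liver SBRT plans against phase-tracked four-dimensional
    plans on respiration-resolved (4DCT-like) image sets. Provides a seedable
    deforming-liver digital phantom with ground-truth displacement fields,
    intensity-based B-spline free-form deformable registration, an analytic
    multi-beam dose surrogate with coverage normalization, deformable dose
    accumulation across respiratory phases, dose-volume histogram metrics
    (Vx, Dmean, Dmax, D95), Lyman-Kutcher-Burman normal tissue complication
    probability with Kutcher-Burman effective-volume DVH reduction, and a
    paired cohort driver with Wilcoxon signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
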