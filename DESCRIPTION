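Package: octsubband
Title: Quantification of the Hyperreflective Sub-Band Posterior to the
    External Limiting Membrane in High-Resolution OCT
Version: 0.1.0
Authors@R:
    person("OCT", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the faint hyperreflective sub-band of the
    photoreceptor myoid zone, just posterior to the external limiting membrane
    (ELM), in high-resolution optical coherence tomography (OCT). Includes a
    parametric simulator of flattened outer-retina OCT volumes (Gaussian band
    model, axial point-spread-function blur, multiplicative speckle with
    volume fusion, foveal geometry, vessel shadows), display preparation
    (Bruch's membrane segmentation and flattening, iterative histogram
    auto-contrast, axial stretching), A-scan peak-intensity ratiometry with a
    fixed-offset fallback and shadow substitution, simulated B-scan visibility
    grading with majority voting, and the cohort statistics battery
    (Kruskal-Wallis, Spearman, Pearson chi-square, Cramer's V, Fisher's exact
    test, Cohen's kappa), tied together in a reproducible pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
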