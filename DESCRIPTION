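Package: mchmap
Title: Non-Parametric Mapping of Forest Mean Canopy Height with Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks non-parametric regression methods for mapping tropical
    forest mean canopy height (MCH) from multi-sensor satellite layers.
    Provides multi-scale Gaussian and local-standard-deviation texture
    features, a maximum-entropy class-probability regressor with a
    power-weighted bias-corrected variant (MEBC), bagged regression forests
    with a two-pass out-of-bag residual-reflection bias correction (RFBC),
    tail-bias diagnostics (MSD1/MSD2), Monte Carlo cross-validation,
    empirical semi-variograms, and synthetic-data generators (tabular
    simulation and spatially autocorrelated landscapes with saturating
    pseudo-satellite bands) so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
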