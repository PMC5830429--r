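Package: chancap
Title: Single-Cell Channel Capacity of GPCR Calcium Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the information channel capacity of GPCR-driven
    calcium signaling in single cells from repeated-stimulation Fura-2
    ratio recordings. Provides peak extraction from raw ratio traces
    (background removal, template-aligned detection of the expected
    pulse peaks, artifact exclusion), maximum-likelihood fitting of a
    per-concentration scaled Student t noise model to replicate
    residuals, per-cell mutual-information maximization by
    Blahut-Arimoto iteration over a quadrature-discretized output (a
    discrete lower bound on the tested concentrations and an
    interpolated estimate over a continuous concentration axis),
    desensitization analysis with a median-residual adaptation
    correction, and a synthetic-data generator reproducing the assumed
    statistical structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    graphics,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
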