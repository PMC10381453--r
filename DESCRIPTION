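Package: specfuse
Title: Multi-Block PLS-DA Data Fusion for Vibrational Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric data fusion for multi-modal vibrational spectroscopy
    (mid-infrared, near-infrared, Raman). Implements per-modality spectral
    preprocessing (Savitzky-Golay smoothing and derivatives, standard normal
    variate, trimming, clipping), one-block and multi-block partial least
    squares discriminant analysis with Frobenius-norm block scaling,
    leave-one-group-out cross-validation with latent-variable selection,
    block-weight and correlation-loading interpretation, and a synthetic
    multi-modal spectrum generator with known ground truth for validating
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
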