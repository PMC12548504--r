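Package: hyperwdecon
Title: Reference-Free Deconvolution of Hyperpolarization Decay in 2D NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and correction of the line broadening that
    hyperpolarized-water (dDNP) experiments imprint on the indirect dimension
    of 2D NMR interferograms. Provides a forward simulator of
    States-hypercomplex BEST-HMQC-like data under a common exogenous
    exponential decay, a neural-network regressor that estimates the decay
    rate directly from indirect-dimension traces without any reference
    signal, deconvolution by division before Fourier transform, and
    quantitative evaluation of the recovered spectra (peak picking,
    linewidths, signal-to-noise ratios, enhancement factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
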