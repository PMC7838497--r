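Package: episcope
Title: Spontaneous EPSC Trains and Calcium-Imaging Population Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nicotinic modulation of spontaneous glutamate
    release and population activity in brainstem slice recordings. Detects
    spontaneous excitatory postsynaptic currents (sEPSCs) in voltage-clamp
    traces and computes binned frequency histograms, baseline-normalised drug
    effects, maximal-effect windows, burst statistics and per-cell
    responsiveness. Turns calcium-imaging movies or ROI fluorescence traces
    into dF/F transients, binary activity rasters, coactivity histograms and
    Monte Carlo surrogate-validated synchrony peaks, with per-cell activity
    comparisons across drug conditions. Includes exact small-sample
    nonparametric tests (Mann-Whitney U, two-sample Kolmogorov-Smirnov,
    Friedman) and a synthetic-data module that emulates the recordings with
    exported ground truth, so every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
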