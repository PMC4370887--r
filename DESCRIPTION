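Package: basr
Title: Burst Analysis Spectroscopy of Liposome Populations and Membrane Fission
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-particle burst analysis spectroscopy (BAS) for quantifying
    membrane fission in free solution. Simulates polydisperse, membrane-labeled
    liposome populations and their photon-count burst traces through a confocal
    detection volume, detects single-particle bursts, reconstructs
    concentration-versus-intensity (BAS) histograms including dilution-series
    merging and Monte Carlo inference of population polydispersity, assembles
    fission time courses with fractional-intensity heat maps and kinetic
    summaries, and computes fluorescence correlation spectroscopy (FCS)
    autocorrelation curves with single-component diffusion fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
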