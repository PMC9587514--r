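Package: spectroct
Title: Spectroscopic and Polarization-Sensitive OCT Biomarkers for Ocular Melanin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chromophore content (retinal melanin in
    particular) from optical coherence tomography (OCT) volumes. Implements the
    slope of the spectral coefficient of variation (SSCoV), a spectroscopic
    biomarker built from a bank of narrow Gaussian spectral windows in k-space;
    the RPE-to-choroid intensity ratio (RC ratio); and degree of polarization
    uniformity (DOPU) depolarization metrics with noise-bias correction.
    Includes the supporting processing chain (spectral reconstruction, annular
    and radial reductions around the optic nerve head, profile normalization
    and alignment, cross-sectional compositing), longitudinal group statistics,
    and a Beer-Lambert speckle simulator for dilution-series phantoms and
    layered retinas so that every stage can be exercised without real OCT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
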