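Package: morphospec
Title: Morpho-Molecular Phenotyping of Single Cells from Raman and
    Refractive-Index Tomography Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free morpho-molecular phenotyping of single cells from
    paired Raman hyperspectral maps and refractive-index tomograms. Provides
    Raman preprocessing (cosmic-spike removal, adaptive smoothness penalised
    least squares baseline correction, Savitzky-Golay denoising, Frobenius
    normalisation), PCA-based cell segmentation and band integrals,
    tomographic morphometry (volume, surface area, footprint, thickness,
    sphericity, dry-mass density and dry mass via the refraction increment),
    a PCA-multiple-linear-regression screen for phenotype-discriminating
    spectral components, exact Mann-Whitney and Pearson correlation group
    statistics, and multinomial-logistic phenotype inference compared by
    likelihood-ratio tests, AIC and leave-one-out cross-validation. A
    synthetic paired-data generator emulates cohorts of labelled cells so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
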