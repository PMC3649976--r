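Package: v1rear
Title: Sparse-Coding Models of Binocular V1 Receptive-Field Development
    Under Abnormal Rearing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the development of binocular primary visual cortex
    (V1) simple-cell receptive fields by unsupervised learning of sparse
    codes from stereo image patches. Provides a synthetic stereo natural-image
    generator, binocular patch sampling, rearing-condition input filters
    (stripe, orthogonal, monocular, alternating, partial-monocular,
    strabismic, and noise mixtures), PCA whitening, three sparse-code
    learners (an overcomplete product of Student-t experts trained by
    contrastive divergence, FastICA, and k-means), and receptive-field
    characterisation (binocularity and 7-point ocular dominance, quadrature
    grating tuning, circular variance, FWHM, spatial-frequency preference,
    and pixel localization), together with population summaries and the
    statistical comparisons between rearing conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    tools,
    utils,
    png,
    yaml,
    jsonlite,
    ica,
    withr
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    tiff
Config/testthat/edition: 3
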