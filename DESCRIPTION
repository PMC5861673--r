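Package: prospectwb
Title: White-Background PROSPECT Modelling and Inversion of Leaf Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inversion of leaf directional-hemispherical
    reflectance measured over a white Teflon background. Implements the
    generalized plate (Stokes N-layer) leaf radiative-transfer model for four
    model generations differing in their chlorophyllian pigment separation,
    couples the leaf volume with a wavelength-independent surface reflectivity
    and the white background, and estimates pigment, water and dry-matter
    contents by bounded multi-start least-squares inversion over 400-2200 nm.
    Also provides the vegetation-index empirical alternative (red-edge
    chlorophyll and shortwave-infrared water indices with leave-one-out
    calibration), agreement metrics for trait retrieval evaluation, a tabular
    dataset reader/writer, and a synthetic data generator with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
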