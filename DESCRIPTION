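Package: kcqi
Title: Composite Quality-Index Construction and Hyperspectral Prediction for Kiwifruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing a kiwifruit comprehensive quality index
    (KCQI) from soluble solids content, firmness and CIELAB colour parameters
    via factor analysis, and for predicting it from visible/near-infrared
    hyperspectral reflectance. Includes a synthetic-data generator that
    reproduces the shelf-life correlation structure and spectral features the
    analysis assumes, ENVI cube input/output with white/dark radiometric
    correction, SPXY sample partitioning, SPA/CARS/random-frog characteristic
    band selection, PLSR, random-forest and one-dimensional convolutional
    network regression backends, and pixel-wise quality-index mapping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    EBImage,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
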