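Package: huePQS
Title: Hue-Spectrum Fingerprinting and Polar Qualification System
    Analysis of Fruit Ripening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assessment of fruit ripening from machine-vision color data.
    Extracts saturation-weighted hue spectra from images of produce on a
    white background, compresses each spectrum to its Polar Qualification
    System (PQS) gravity point, and computes the reference instrument
    indices used alongside vision data in postharvest studies: the
    absorbance-difference DA-index and the acoustic firmness coefficient.
    Provides the statistical layer used to compare maturity groups and
    1-MCP treatment arms (factorial ANOVA with Type III sums of squares,
    Levene variance-homogeneity routing, Tukey HSD and Games-Howell post
    hoc tests with compact letter displays, Pearson and Spearman
    correlation matrices), and a calibrated synthetic tomato-ripening
    study generator with a ground-truth image renderer for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
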