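Package: dragonmorph
Title: Quantification and Classification of Throat Colour Morphs in Polymorphic Lizards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for objective quantification of discrete throat colour
    morphs in the tawny dragon lizard (Ctenophorus decresii) and similar
    polymorphic agamids. Implements receptor-noise-limited chromatic and
    achromatic contrast (just noticeable differences) of reflectance
    spectra against a neutral grey background, calibration (linearization
    and grey-standard equalization) and threshold segmentation of throat
    photographs into red/yellow/grey layers, canonical discriminant
    classification of morphs with Wilks' lambda and leave-one-out
    cross-validation, hormone and colour time-course statistics (blocked
    ANOVA with Tukey-adjusted contrasts, exact r x c frequency tests,
    Benjamini-Hochberg FDR, quadratic mixed-effects trajectories), and
    seeded generators of synthetic spectra, images and longitudinal panels
    with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    lme4,
    emmeans,
    jsonlite,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
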