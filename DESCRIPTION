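Package: camonest
Title: Predator-Vision Camouflage Metrics and Nest Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies background-matching camouflage of ground-nesting bird
    clutches from calibrated multispectral (visible + ultraviolet) images and
    relates it to nest survival. Provides camera linearization and grey-standard
    reflectance calibration, UV/visible alignment, polynomial mapping of camera
    channels into predator cone-catch quanta (dichromat, trichromat and
    tetrachromat visual systems), luminance and contrast metrics, 32-level
    luminance-histogram and 17-scale FFT bandpass pattern-energy differences,
    receptor-noise (Vorobyev-Osorio) colour discrimination with local/global
    colour clustering, Kaplan-Meier and Cox proportional-hazards survival
    analysis of predation, and a synthetic-data module that generates calibrated
    scenes with controllable camouflage mismatch and nest-fate tables for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    survival,
    tiff,
    png,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
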