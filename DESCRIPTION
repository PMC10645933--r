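Package: pbmstudy
Title: Blinded Behavioral and Histological Analysis Pipeline for a Murine
    Photobiomodulation Study
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze a blinded preclinical photobiomodulation study in
    an Alzheimer's mouse model. Computes trajectory-derived memory metrics
    (novel object recognition discrimination index, Y-maze spontaneous
    alternation, Morris water maze training and probe metrics), quantifies
    amyloid plaque load and the peri-plaque microglial response with an
    annulus intensity ratio on fluorescence sections, applies the study's
    normality-gated statistical decision procedure, and provides study-design
    utilities (sex-balanced blinded randomization, light-dose arithmetic, fur
    attenuation). Ships seeded synthetic-data generators for arena
    trajectories and stained sections with exported ground truth, so every
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
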