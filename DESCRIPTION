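Package: renotex
Title: GLCM Texture Analysis and Neural-Network Staging of Renal Sonograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for computer-aided staging of chronic
    kidney disease from B-mode renal ultrasound. Texture is quantified with
    gray-level co-occurrence matrices (19 second-order descriptors per region
    of interest, angle-averaged over four orientations) computed from three
    anatomical windows (cortex, corticomedullary boundary, medulla), fused
    with kidney size into a 58-dimensional feature vector, and classified
    into three disease classes (normal, mild-and-moderate, severe) by a small
    feed-forward network with early stopping. Because clinical sonograms are
    private, the package ships a seeded synthetic cohort generator that
    emulates the described echo structure (correlated multiplicative speckle,
    rising cortical echogenicity and fading corticomedullary contrast with
    severity, per-class kidney-size distributions), so every stage is
    testable end to end without patient data.
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
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
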