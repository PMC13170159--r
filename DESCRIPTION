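Package: holoGram
Title: Lensless Digital Holographic Microscopy Simulation and Gram Stain
    Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates lensless in-line digital holographic microscopy of
    Gram-stained blood-culture smears and reconstructs and interprets the
    resulting holograms. Provides a seeded synthetic specimen generator
    (Gram-negative bacilli, Gram-positive cocci in clusters or in
    pairs/chains, red-cell background, stain-quality variation), an angular
    spectrum scalar-diffraction forward model with sensor noise,
    computational autofocus by contrast maximization, multi-wavelength
    Gerchberg-Saxton phase retrieval over an axial stack with per-object
    focal selection and color composition, rule-based hologram quality
    triage, classical segmentation-based Gram morphology calling with
    attention maps, and confusion-matrix evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
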