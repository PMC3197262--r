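Package: stentmra
Title: Simulation and Scoring of Stent Lumen Visibility in Contrast-Enhanced MR Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how peripheral arterial stents obscure their own
    lumen in contrast-enhanced magnetic resonance angiography. The package
    builds voxelised phantoms of gadolinium-filled tubes containing wire-mesh
    stents embedded in gel, synthesises 3D spoiled gradient-echo images with
    susceptibility-induced intravoxel dephasing (Fourier dipole-kernel field
    maps) and RF-shielding-modified excitation, extracts three quantitative
    lumen-visibility measurements (relative in-stent signal intensity,
    minimal/maximal visible lumen diameter, and signal homogeneity), and
    converts them into a three-category ordinal grading with an overall
    3-9 point score. Ships a transcription of a published 22-stent in vitro
    measurement set so the grading rules can be applied to bench data
    without re-imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
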