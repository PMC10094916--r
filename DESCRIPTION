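Package: hyperskin
Title: Hyperspectral Texture and Reflectance Analysis of Skin Hyperpigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies changes in skin hyperpigmentation from hyperspectral
    image cubes. Reads and writes cubes in the ENVI header plus raw-binary
    convention, calibrates raw counts to reflectance against a white reference,
    converts region-of-interest reflectance to gray levels, computes gray-level
    co-occurrence matrix (GLCM) brightness, contrast and homogeneity, extracts
    maximum/average/minimum reflectance profiles and band statistics at the
    melanin analysis wavelength (654 nm by default), and aggregates paired
    before/after cohorts with medians, quartiles, direction counts and exact
    Wilcoxon signed-rank tests. Includes a synthetic-cohort generator that
    synthesizes textures with prescribed co-occurrence statistics, plus a
    packaged 12-patient preset whose cohort summaries match a published
    depigmentation study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
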