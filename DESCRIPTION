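Package: metaspread
Title: Tumor Growth, Vessel-Tree Geometry and Metastatic Spread Under Therapy
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for analysing xenograft tumor-growth experiments with a
    colonization (Iwata-type) model of metastatic spread. Fits exponential
    growth curves to palpated tumor-volume series corrected against necropsy
    weight, calibrates a colonization coefficient from a reference animal,
    infers the fractal dimension of the tumor vasculature from disseminated
    (DTC) and circulating (CTC) tumor-cell counts, simulates seeding as an
    inhomogeneous Poisson process, models cisplatin chemotherapy and
    hypofractionated radiotherapy effects on growth and dissemination,
    quantifies microvessel density from stained histology rasters by
    region growing and k-means segmentation in CIE L*a*b* space, and ships
    synthetic-cohort and synthetic-slide generators with recorded ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    png,
    optparse
Config/testthat/edition: 3
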