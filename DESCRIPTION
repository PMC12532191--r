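Package: memquant
Title: Quantification of Cholesterol/Sphingomyelin Membrane Nanodomain Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for quantifying the lateral organization of
    cholesterol/sphingomyelin-enriched domains at the plasma membrane.
    Implements quantitative single-molecule localization microscopy (qSMLM)
    processing with fiducial-based drift correction, blinking-corrected
    molecule counting, pair-correlation cluster-radius estimation and
    density-seeded cluster assignment; fluorescence correlation spectroscopy
    (FCS) autocorrelation and model fitting with triplet blinking and mixed
    free-3D plus membrane-2D diffusion, observation-volume calibration,
    membrane surface density and molecular brightness; ratiometric calcium
    transients (Fura Red ratio) and generalized polarization (GP) membrane
    fluidity from line profiles; a split-resampling sampling-sufficiency
    test and standard group comparisons; and synthetic-data generators with
    known ground truth for every input so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    data.table,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
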