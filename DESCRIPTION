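Package: zorbkit
Title: Hydrodynamics and Quantification of Gliding-Bacterial Microcolony Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the collective motility of surface-associated
    bacterial microcolonies ("zorbs") propelled by semi-vertical base cells.
    Provides a meshfree two-dimensional Stokes solver based on generalized
    moving least squares (GMLS) collocation for multiple rigid bodies inside a
    circular microdrop, with adaptive refinement and an independent analytic
    oracle for eccentric rotating-cylinder (Wannier) flow; the force-balance
    chain linking single-cell gliding drag, per-cell stroking force, base-cell
    scaling laws and the net force percentage (NFP) of a moving microcolony;
    an image-based quantification pipeline for time-lapse microcolony movies
    (dual-mask segmentation, linear-assignment tracking with merge/split
    events, volume-weighted morphometrics, base-cell maxima counting,
    power-law fitting, neighbour-weighted cell orientation statistics); and a
    synthetic-data module that generates movies, base-cell images, velocity
    samples and cell fields with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
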