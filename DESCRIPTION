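Package: plexid
Title: Projection-Defined Fluorophore Identity Assignment for Multiplexed
    Spectral Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns projection-defined fluorophore identities to
    calcium-active neurons imaged through a GRIN lens. Co-registers
    miniscope fields of view with multiplexed confocal spectral stacks
    (6 excitation lasers x 34 emission bins = 204 channels per region of
    interest), linearly unmixes per-ROI spectral fingerprints against a
    reference library by non-negative least squares, and classifies
    identities with a per-subject dual-pass adaptive threshold. Includes
    polynomial models of GRIN-lens chromatic aberration and transmission,
    a synthetic-data generator for fingerprints, ROI spectral datasets and
    co-registered image pairs, a Monte-Carlo robustness simulation engine,
    and peri-event behavioral selectivity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
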