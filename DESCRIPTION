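Package: filmdose
Title: Radiochromic Film Dosimetry of Breast Dose in Coronary Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating breast organ dose from radiochromic film
    exposed inside the breast slabs of an anthropomorphic torso phantom
    during C-arm fluoroscopy. Fits monotone pixel-value-to-dose calibration
    curves (manual and automatic-brightness-control acquisition modes, with
    solid-state to ionization-chamber detector correction), converts scanned
    film to 2D absorbed-dose maps, extracts circular-mask regional mean
    doses, aggregates per-slice doses into mass-weighted per-breast and
    overall organ doses, normalizes them by dose-area product (DAP) into
    conversion factors, and reconstructs procedure-level breast dose from
    acquisition logs via per-angulation factor tables. A synthetic
    phantom/beam/film generator provides ground-truth exposures for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
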