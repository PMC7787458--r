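Package: ivmtrack
Title: Motility and Contact Analysis of Intravital T Cell Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies T cell-tumor cell engagement from time-lapse 3D cell
    trajectories as exported by surface-tracking software. Computes per-track
    motility indices (speed, track displacement, meandering index, arrest
    coefficient), detects T cell-tumor contact episodes from centroid
    proximity and summarizes contact duration and long-contact fractions,
    measures peripheral T cell recruitment density, and compares groups with
    the nonparametric and Welch tests standard in intravital imaging studies.
    Includes a two-state (free / engaged) persistent-random-walk simulator of
    3D time-lapse movies with named presets emulating freely searching versus
    antibody-engaged T cell behavior, providing ground truth for every
    downstream metric, plus the transwell chemotaxis percent-migration and
    fold-change arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
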