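Package: cardiospinal
Title: Spinal Neuronal and Cardiac Electrogram Analysis of Myocardial
    Ischemia and Spinal Cord Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how spinal cord stimulation modulates
    spinal neuronal responses to acute myocardial ischemia. Computes
    activation recovery intervals, ST-segment elevation, ischemic-zone
    masks and dispersion of repolarization from multichannel unipolar
    epicardial electrograms; detects firing-rate changes in sorted spike
    trains with a Skellam-based two-window test; identifies antidromically
    activated intermediolateral (IML) preganglionic neurons and
    mechanosensitive/nociceptive response classes; and measures pairwise
    spike synchrony with a jitter-surrogate-normalized synchrony index.
    Includes seeded synthetic-data generators with known ground truth for
    electrograms and spike populations, and a study pipeline comparing
    ischemia responses before and after spinal cord stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
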