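Package: nanosar
Title: Structure-Activity Analysis for ssDNA-SWCNT Optical Nanosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence screening of catecholamine
    analytes against single-walled carbon nanotube (SWCNT) sensors wrapped in
    single-stranded DNA. Quantifies blank-subtracted, integrated and
    dopamine-normalized optical responses (dF/F) and assigns response
    categories; correlates responses with molecular descriptors (Hammett
    sigma constants, HOMO energies, reduction potentials) and compares
    charge groups; models protonation microspecies fractions over pH; and
    computes molecular-dynamics trajectory metrics: buried-surface contact
    areas from Shrake-Rupley SASA, cylindrical surface distances, bound-time
    percentages, residence times from binding-event segmentation, aryl
    stacking distances, polar-group distance distributions with 4 Angstrom
    areas-under-the-curve, radial distribution functions, hydrogen-bond
    counts and binding-mode assignment. A seeded synthetic-data module
    generates emission spectra with prescribed dF/F and cylinder-world
    trajectories with known Markov binding kinetics for estimator
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    readr
Config/testthat/edition: 3
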