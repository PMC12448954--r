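Package: uvburden
Title: Mutation Burden and Skin-Cancer Surveillance Modelling for NB-UVB Phototherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the somatic mutation burden induced in human epidermis by a
    course of narrowband ultraviolet B (NB-UVB) phototherapy and projects the
    lifetime number of NB-UVB exposures at which skin-cancer surveillance should
    begin. Ships a per-patient cohort of paired pre/post-treatment duplex-sequencing
    burden measurements together with phototherapy course dosimetry; converts
    radiant exposure to standard erythema doses via the CIE erythema action
    spectrum; computes the cohort comparison statistics; fits the exponential
    dose-response model S(MED) = A * exp(-b * MED^2) by log-linear least squares
    with cluster-bootstrap uncertainty; and tabulates projected surveillance
    thresholds over minimal erythema dose, sun-behaviour and horizon grids.
    Includes a synthetic-cohort generator with known ground truth for
    parameter-recovery and coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
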