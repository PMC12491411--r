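Package: reactkit
Title: Reactivity Descriptors, Mass Annotation and Radical-Scavenging
    Analysis for Natural-Product Antioxidant Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for desk-scale antioxidant structure-activity
    studies of natural products. Annotates LC-MS peak lists against a
    candidate library by monoisotopic mass and ppm error, computes the nine
    conceptual-DFT global reactivity descriptors (ionization potential,
    electron affinity, hardness, softness, electronegativity, chemical
    potential, electrophilicity, electrodonating and electroaccepting
    power) from vertical neutral/cation/anion energies, converts DPPH
    microplate absorbances to percent inhibition and estimates IC50 with
    replicate spread, and joins descriptors with activity for rank
    correlation and report tables. Seeded generators produce synthetic peak
    lists, energy triples and dose-response plates with known ground truth
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
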