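Package: calcitile
Title: Design and Evaluation of Protein Templates for Calcium Carbonate Nucleation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating flat helical-repeat protein
    templates that nucleate calcium carbonate. Generates idealized
    helix-turn-helix repeat backbones with tunable inter-repeat spacing,
    implements a constrained Monte-Carlo flattening protocol, extracts and
    recodes carboxylate surface arrays, builds Miller-indexed calcite and
    vaterite surface slabs and their two-dimensional ion nets, scores
    epitaxial lattice matching between template arrays and mineral surfaces,
    performs repeat-symmetric Monte-Carlo rigid-body docking with a
    baseline-subtracted binding score, and provides classical
    nucleation-theory barriers, carbonate speciation and saturation indices,
    and the quantitative analysis formulas used to interpret templated
    mineralization experiments.
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
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
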