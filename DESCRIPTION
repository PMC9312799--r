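Package: solpep
Title: Solubility-Aware Gradient-Based Design of Protein-Binding Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale engine for hallucinating peptide binders under an
    explicit solubility constraint. Peptide sequences are relaxed to
    per-position probability distributions over the twenty canonical amino
    acids and optimized by gradient descent through a three-stage
    soft/annealed/hard schedule against a pluggable binding oracle, while a
    differentiable solubility loss built from normalized amino-acid indices
    (a membrane-buried hydrophobicity scale, the Kyte-Doolittle hydropathy
    scale, and the solubility-weighted index) is co-minimized with a tunable
    weight. Includes a deterministic surrogate binding oracle emulating the
    hydrophobic interface preference of structure-prediction oracles, random
    and saturation single-substitution baseline generators, dual-threshold
    candidate filtering on solubility and docking affinity scores,
    position-frequency-matrix construction with sequence-logo plots, and a
    seeded fixture generator so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
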