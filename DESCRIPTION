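Package: switchmap
Title: Thermodynamic Modelling and Array-Based Quantification of Stand-Alone RNA Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and quantifying stand-alone (self-contained,
    reversible) RNA switches that couple a small-molecule input aptamer to a
    fluorescent reporter output. Implements a closed-form three-state
    equilibrium model of switch response with its thermodynamic
    activation-ratio ceiling (1 + L/Kd), a simplified ligand-aware
    partition-function engine for RNA secondary structure (base-pair
    probabilities, split-aptamer "x ratio" scores, functional-element
    annotation, arcplot export), cluster-level Langmuir binding-curve
    quantification in the style of massively parallel array assays (median
    aggregation, paired +/- ligand Kd estimation, bootstrap activation-ratio
    intervals, boxplot round summaries, replicate concordance, ligand-toggling
    reversibility analysis), sequence-space analysis of design collections
    (edit distances, modification families, distance trees), and seeded
    synthetic-data generators with retained ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    ape,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
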