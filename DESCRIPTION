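Package: flnmod
Title: Modular Analysis of Disease-Related Functional Linkage Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds confidence-thresholded functional linkage networks from
    STRING-style weighted edge lists seeded with disease core proteins,
    enumerates functional modules as maximal cliques, scores each module for
    annotation homogeneity (pathway, subcellular localization, disease) with
    an entropy-based redundancy statistic and permutation significance,
    combines the features through a nonlinear model whose coefficients are
    fitted by a genetic algorithm supervised with planted ideal modules,
    assembles a condensed network from the top-ranked modules, decomposes its
    biological processes into a maximal non-overlapping Gene Ontology term
    configuration, and derives a permutation-tested disease-disease overlap
    network. A deterministic synthetic-data generator with known ground truth
    makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
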