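Package: molcomplex
Title: Graph-Degree Molecular Complexity Scores MC1 and MC2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the molecular complexity measures MC1 (fraction of
    non-divalent heavy atoms in the molecular graph) and MC2 (number of
    non-divalent heavy atoms, not counting the C=O of carboxyl derivatives
    such as acids, esters, amides, carbonates, carbamates and ureas) from
    SMILES strings and SDF records. Supports polymer repeat units written
    with dummy-atom attachment points, deterministic synthetic structure
    generators with closed-form expected scores, a measure-comparison
    harness (pairwise squared Pearson correlations and distribution
    summaries over a molecules-by-measures score table), and a batch
    command-line interface for scoring structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    graphics,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
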