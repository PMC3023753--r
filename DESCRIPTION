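Package: bruisemap
Title: Two-Stage Mixed-Model Candidate-Gene Association Mapping for
    Tetraploid Potato Tuber Bruising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene association mapping of tuber
    bruising and related agronomic traits in panels of tetraploid potato
    clones evaluated in multi-environment field trials. Implements
    derived-trait construction (bruising index from discoloration
    category counts, starch-corrected bruising as the residual of
    bruising on specific gravity), stage-one REML variance-component
    estimation with entry-mean heritability and generalized-least-squares
    adjusted entry means, marker-based kinship (Loiselle-type moment
    estimator on dominant fragment frequencies) and principal-coordinate
    population structure, the PK (Q+K) mixed-model single-marker scan
    with kinship-structured polygenic effects and heteroscedastic
    residuals, and multi-locus forward selection with
    explained-genetic-variance accounting. A synthetic-data generator
    emulates the structured tetraploid trial design so the whole
    pipeline is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
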