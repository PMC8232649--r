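Package: comorbidome
Title: Transcriptomic and Network Comorbidity Analysis Between
    Neurodegenerative Disorders and Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying molecular comorbidity between disease
    pairs from case/control transcriptomes. Implements random-effects
    differential-expression meta-analysis (Hedges' g effect sizes combined
    by the DerSimonian-Laird estimator), four-quadrant Fisher intersection
    tests that classify disease pairs as same-direction or
    opposite-direction deregulated, overrepresentation and preranked gene
    set enrichment analysis with permutation-based normalized enrichment
    scores, interactome disease-module localization and separation
    statistics with degree-preserving null models, and consensus drug
    perturbation signatures matched against disease profiles by rank
    correlation. A synthetic-data module generates every input with planted
    ground truth so the full pipeline is testable end to end.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
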