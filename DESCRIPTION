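Package: reosig
Title: Individualized Prognostic Signatures from Relative Expression Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives stemness-related gene sets from single-cell expression
    profiles, subtypes bulk tumour cohorts by single-sample gene-set
    enrichment (ssGSEA), discovers subtype-stable and reversal relative
    expression ordering (REO) gene pairs with a cumulative binomial model,
    and builds an individualized gene-pair prognostic signature by
    C-index-guided forward search with a half-voting classification rule.
    Because the signature depends only on within-sample expression
    orderings, predictions are invariant to monotone per-sample batch
    distortions and require no cohort-level normalisation. Includes a
    synthetic-data generator with planted ground truth for end-to-end
    validation, survival evaluation (Kaplan-Meier, log-rank, Cox
    proportional hazards, Harrell's concordance index), and a config-driven
    pipeline runner.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
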