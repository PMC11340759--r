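Package: fmtlink
Title: Donor Strain Engraftment Tracking and Outcome Linking for Fecal
    Microbiota Transplantation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking donor-strain engraftment after fecal
    microbiota transplantation (FMT) from strain-level phylogenetic
    distances, and for linking engraftment to clinical outcomes and plasma
    metabolites.  Estimates per-species strain-identity thresholds from
    related versus unrelated sample-pair distance distributions (Youden's
    index and percentile rules), assigns the origin of post-FMT strains
    within donor/pre/post triads, computes strain-sharing rates and
    engraftment metrics, fits ridge-regularized canonical correlation
    models with leave-one-out penalty tuning and correlation-circle
    inner-product pair selection, and tests selected engraftment-outcome
    links with linear mixed-effects models (Satterthwaite degrees of
    freedom), Procrustes permutation tests and Spearman correlations.
    Includes a synthetic-cohort generator with known ground truth and a
    file-based pipeline driver for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    lme4,
    lmerTest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
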