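Package: abasubtypes
Title: Subtyping Accelerated Brain Aging from Multimodal Brain-Age Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the heterogeneity of accelerated brain
    aging from tabular imaging-derived phenotypes (IDPs). Fits per-modality
    penalized linear brain-age models with age-bias correction, stratifies
    subjects into accelerated (ABA) and resilient (RBA) brain-aging groups by
    the sign of the brain-age gap across modalities, discovers ABA subtypes
    with a semi-supervised convex-polytope of max-margin linear classifiers
    (HYDRA) selected by cross-validated cluster stability (adjusted Rand
    index), and characterizes subtypes with reference-anchored Z-scores,
    covariate-adjusted ANOVA under Bonferroni control, Dunnett-style
    contrasts, and chi-square tests. Includes a seeded synthetic cohort
    generator emulating the multimodal IDP table structure so the whole
    pipeline is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    multcomp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
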