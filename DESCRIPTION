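Package: snfmark
Title: Multi-Omics Biomarker Discovery via Similarity Network Fusion and
    Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates DNA methylation, mRNA and miRNA expression layers of a
    patient cohort by similarity network fusion (SNF), selects the number of
    disease subtypes with a similarity-space clustering-quality ratio, ranks
    features by the concordance (normalized mutual information) between
    single-feature and fused clusterings (ranked SNF), intersects the
    top-ranked gene sets across layers into essential genes, assembles a
    TF-miRNA-target regulatory network from interaction tables, ranks hub
    nodes by maximal clique centrality, and validates candidate biomarkers
    with Kaplan-Meier / log-rank survival analysis, chi-square stage
    association and ROC/AUC. Ships a synthetic multi-omics cohort generator
    with planted subtypes, informative features and network hubs so the whole
    pipeline is testable without external data.
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
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
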