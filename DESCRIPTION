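Package: migrn
Title: Mutual-Information Gene Regulatory Network Inference and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers gene regulatory networks from expression matrices with
    three mutual-information based methods -- C3Net (one maximum-MI edge per
    gene, permutation-null significance), BC3Net (bootstrap-aggregated C3Net
    with a binomial consensus test) and an ARACNE-style procedure (significant
    MI graph thinned by the data processing inequality) -- using the Gaussian
    Pearson estimator I = -1/2 log(1 - rho^2). Provides rank-based copula
    preprocessing, probe-to-gene median summarization, network centralities
    and global graph statistics, edge-overlap tables, gene-pair enrichment
    analysis (hypergeometric), a permutation test on gene-set mean degree
    centrality, comparison against reference interaction networks with
    permutation significance and sliding-window degree correlation profiles,
    and a synthetic-data module that generates ground-truth networks,
    expression data, gene sets and reference networks for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
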