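Package: crossmb
Title: Cross-Species Rank Comparison of SHH-Subtype Medulloblastoma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares sonic hedgehog (SHH) subtype medulloblastoma expression
    profiles across mouse models and human tumor cohorts. Each dataset is
    reduced to group-median, gene-level overexpression values (row-centered or
    cerebellum-normalized), genes are quantile-ranked by SHH-group
    overexpression, ranks are averaged per species over homologous gene pairs,
    and human-minus-mouse rank differences feed a from-scratch preranked gene
    set enrichment analysis with a permutation family-wise error rate. Includes
    rank-invariant-set between-array normalization, max-mean probeset-to-gene
    collapse, a dataset correlogram, a coexpression rank-concordance check, and
    a synthetic multi-dataset generator with planted ground truth for offline
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
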