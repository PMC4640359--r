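Package: netshift
Title: Network Rewiring Analysis of Paired-Condition Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired before/after gene-expression
    contrasts, built around four stages: overlap of differentially
    expressed gene sets across datasets with hypergeometric testing;
    construction of a pruned "disrupted" protein-interaction subnetwork
    seeded by the commonly differentially expressed genes; tree-ensemble
    (random-forest importance) inference of transcription-factor
    regulatory networks per condition with a per-factor "increased
    influence" shift statistic; and hypergeometric gene-set enrichment
    against GMT collections. A synthetic-data module generates
    negative-binomial count matrices with a controlled shared
    differential-expression structure, scale-free interactomes with a
    designated mega-hub, and ground-truth regulatory networks, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    jsonlite,
    yaml,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
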