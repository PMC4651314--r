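Package: difcore
Title: Differential Co-Expression Network Analysis with k-Core Hub Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-condition RNA-seq analysis pipeline for small replicated
    designs: FASTQ quality filtering, negative-binomial differential
    expression with fold-change and FDR filters, Fisher's exact test gene-set
    enrichment split by direction of change, per-condition Pearson
    co-expression networks, degree and k-core decomposition, and the
    differential k-core (dif-k-core) statistic for ranking hub genes whose
    network centrality differs between conditions. Includes 2^-ddCt qPCR
    relative quantification with RNA-seq concordance checks, and a synthetic
    data module that generates negative-binomial count matrices with planted
    fold changes, copula-injected co-expression blocks, planted enriched gene
    sets, FASTQ reads and Ct tables, so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
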