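Package: rumilink
Title: Host-Microbiota Integration of Rumen Mucosal 16S and Epithelial
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the structure of a mucosal microbial community to host
    epithelial gene expression in small paired designs. Provides OTU-table
    processing (count filtering, taxonomic aggregation, relative abundance,
    Shannon diversity, analytic rarefaction, Bray-Curtis ANOSIM with
    exhaustive label enumeration), an RPKM and log2 fold-change screen for
    differential expression, a Spearman co-expression network around seed
    genes with exact small-n permutation p-values, and a from-first-principles
    constrained correspondence analysis (CCA) that uses seed-gene expression
    as environmental constraints, with genus centroids for interpretation.
    A paired synthetic-data generator with planted ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
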