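Package: liftmerge
Title: Reconcile and Merge Lifted Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unifies two gene-annotation sets placed on the same genome
    assembly: a query set transferred by a liftover tool (in one or more
    flank variants) and a target set native to the assembly. Computes
    bedtools-style fractional gene overlaps, selects the best lift per
    gene, classifies gene fates (matched, rescued, intergenic, unmapped),
    merges gene models into a unified GFF3, detects complex many-to-many
    loci via a bipartite overlap graph, calibrates the overlap threshold
    from known-equivalent gene pairs, and emits an identifier translation
    table. Includes a seeded synthetic-fixture generator with analytic
    ground truth so the whole protocol is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
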