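Package: sweepcss
Title: Integration of Selection-Sweep Studies into Confirmed Selective Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates selective-sweep intervals reported by multiple
    labelled studies into confirmed selective sweeps (CSS), classifies them
    as production- or adaptation-associated by supporting-study
    proportions, annotates positional candidate genes (GTF) and QTL
    (QTLdb-style GFF) within CSS flanking intervals, performs
    hypergeometric QTL and GO over-representation with FDR and database
    filters, reduces redundant GO terms via Wang semantic similarity, and
    selects hub genes by betweenness quantile in gene-term networks.
    Includes seeded synthetic-data generators with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
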