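Package: placimprint
Title: Allele-Specific Expression and Imprintome Analysis for Reciprocal-Cross Placental RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting parent-of-origin gene expression in the rodent
    placenta from reciprocal-cross RNA-seq data. Implements maternal-tissue
    contamination estimation from balanced genes and mixture-model correction of
    parent-of-origin bias scores, hierarchical imprintome calling with
    replication and triage filters, zFPKM-based layer-induced expression
    scoring, parent-of-origin partitioning of bisulfite reads with CpG-level
    differential methylation calling, and outgroup polarization of expression
    divergence. A synthetic-data generator with known ground truth (negative
    binomial counts, per-sample maternal contamination, cis and imprinting
    effects, imprinted X-chromosome inactivation, bisulfite reads) makes every
    stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    edgeR
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
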