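Package: methpath
Title: Methylation-Pathway Classification of Transposable Elements and
    Small RNA Phasing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify transposable elements (TEs) by the dependence
    of their CHH methylation on the chromomethylase (CMT2) or RNA-directed
    DNA methylation (DRM2) pathways from per-cytosine bisulfite reports,
    to quantify size-selected 24-nt small RNA expression (rpkm normalized
    to 18-28 nt totals) and ChIP log2 enrichment with input subsampling,
    to profile small RNA around nucleosome dyads and estimate the
    nucleosome repeat length from autocorrelation, to assemble per-TE
    epigenomic feature matrices for random-forest discrimination of
    chromatin states, and to run GC-sorted binned association analyses,
    correlation matrices and PCA. A seeded synthetic-epigenome generator
    (toy genome, TE annotations, nucleosome dyads, genotype-conditioned
    methylomes, small RNA and ChIP read sets) makes every pipeline stage
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
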