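Package: mesia
Title: Reproducibility-Aware Integration of Multi-Replicate Epigenome Peak Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage consensus peak calling for multi-replicate ATAC-seq and
    related epigenome assays. Stage 1 scores every replicate pair for
    reproducibility by rescue analysis (consistent-peak counts between true
    replicates versus pooled pseudo-replicates) and screens each replicate for
    internal bias by self-consistency of its pseudo-replicate halves, using an
    irreproducible discovery rate (IDR) style copula mixture engine. Stage 2
    intersects the consistent regions of passing pairs into base peaks, filters
    peaks by the base-peak medians of summit offset ("peak point") and Q value,
    and merges the survivors across all passing pairs into an optimal consensus
    set. Ships a windowed Poisson peak caller so the full pipeline runs without
    external binaries, comparator algorithms (naive length overlap and
    non-overlapping maximum signal), a replicate-design simulator for
    benchmarking, and promoter-annotation evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
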