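Package: introScan
Title: Introgression and Selection Scans for Population Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises wild-relative introgression in
    population genotype data and tests whether introgressed regions were under
    subsequent selection. Implements Patterson's D and the f4-ratio with
    block-jackknife significance, sliding-window fdM scans, five-taxon
    DFOIL-style direction-of-gene-flow tests, population branch statistic (PBS)
    selection scans with Monte-Carlo permutation nulls, windowed nucleotide
    diversity, dxy and FST (Hudson and Weir-Cockerham estimators), haplotype
    diversity, and the interval algebra that intersects introgressed and
    selected regions and annotates them against gene and QTL tracks. A
    hierarchical drift simulator with explicit admixture-tract bookkeeping
    provides ground truth for every statistic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
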