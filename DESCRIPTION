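Package: plasmasnv
Title: Somatic SNV Calling and Tumor Fraction Estimation from Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects low-frequency somatic single-nucleotide variants in plasma
    cell-free DNA sequencing data using a joint-genotype mixture model over
    tumor-derived and normal cfDNA, with matched white-blood-cell germline data
    as reference. Mutation clusters are discovered iteratively in decreasing
    order of their cfDNA frequency; candidate sites pass through multi-layer
    error suppression (overlapping read-mate consensus, site-level filters with
    an exact binomial VAF test, a misalignment co-occurrence filter aware of
    non-random cfDNA fragmentation, and a random-forest read-level error
    classifier). Downstream utilities compute the tumor fraction via natural
    breaks on variant allele frequencies, blood tumor mutational burden (bTMB)
    and its truncal variant, and cross-sample confirmation rates. A synthetic
    read/pileup generator with ground truth supports simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    optparse,
    pROC,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
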