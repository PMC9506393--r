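Package: brilqtl
Title: Recombination Bin Maps and Ridge-Regression QTL Scans for Backcross
    Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genotype-to-candidate-gene inference chain for seedling
    cold-tolerance mapping in a backcross recombinant inbred line (BRIL)
    population: meiosis and population simulation with known ground truth,
    genotyping-by-sequencing style observation noise, SNP quality filtering
    (missingness and minor allele frequency), sliding-window recombination
    bin-map construction with block masking and nearest-flank imputation,
    Haldane genetic-map building, ridge-regression genome scans with peak-bin
    QTL calling and LMG relative-importance decomposition of the phenotypic
    variance explained, TPM quantification and differential-expression
    time-course set algebra, hypergeometric term enrichment, and
    QTL-interval candidate-gene prioritization including promoter allele
    comparison and motif-disruption screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
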