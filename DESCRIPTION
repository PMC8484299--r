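Package: popsweep
Title: Two-Group Selective Sweep Scans from Resequencing SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end population-genomic contrast of two groups of
    resequenced diploid individuals: hard SNP quality filtering from VCF,
    windowed nucleotide diversity, Weir-Cockerham Fst and Tajima's D,
    linkage-disequilibrium decay, a joint Z(Fst) by log2 diversity-ratio
    top-quantile selective-sweep scan with region merging and gene overlap,
    group-diagnostic SNP marker screening, SNP region annotation against
    GFF3 gene models, and population structure via neighbor-joining trees
    and GRM-based principal components. Includes a forward Wright-Fisher
    simulator of two-population panels with drift, recombination and an
    optional selective sweep for calibration and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
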