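Package: polyscan
Title: Composite Two-Population Divergence Scans for SNPs, Structural
    Variants and Short Tandem Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-track genome divergence scan between two populations:
    sliding-window SNP statistics (nucleotide diversity, absolute divergence,
    Hudson FST, Tajima's D, iHS, xpEHH) combined into the decorrelated
    composite of multiple signals (DCMS) with robust-model significance and
    FDR control; per-locus Weir-Cockerham FST outlier detection for
    structural variants; per-locus Jost's D outlier detection for short
    tandem repeats. Includes gene-proximity annotation with permutation
    enrichment, fixed-difference detection with a minimal coding-effect
    classifier, candidate-gene cross-referencing, and a synthetic
    two-population dataset generator with planted divergent loci for
    end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    vcfR,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
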