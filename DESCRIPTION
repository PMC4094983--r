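Package: segphase
Title: Fast Segmented Haplotype Phasing for Long Genotype Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Phases long diploid SNP genotype sequences into haplotypes with a
    divide-and-conquer strategy: sequences are cut into fixed-size segments,
    each segment is phased by a three-phase core (linkage-disequilibrium
    chaining of heterozygous sites, scalable sliding-window orientation
    refinement, and a maximum-parsimony hill climb), and adjacent segment
    results are joined by a weight-based sliding-window merge with explicit
    handling of heterozygote-free boundary cases. Includes switch error rate
    and individual error rate evaluators, a neutral-coalescent block
    simulator for generating truth haplotypes, readers for plain-text
    genotype matrices, Hudson ms output and minimal diploid VCF, and a
    command-line interface. Serial and multi-worker runs produce identical
    output for a given seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
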