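Package: popsweep
Title: Population-Genomic Diversity, Inbreeding and Selection-Signature Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-variant-calling population-genomics toolkit for multi-population
    resequencing studies: SNP hard-filtering and site filtering from phased multi-sample
    VCFs; windowed nucleotide diversity, individual heterozygosity and method-of-moments
    inbreeding; runs of homozygosity by a two-state hidden Markov model with F_ROH;
    Weir-Cockerham fixation index per site and in sliding windows; linkage-disequilibrium
    decay curves and PLINK-style LD pruning; principal component analysis and a
    binomial-likelihood admixture model with cross-validation; and haplotype-based
    selection scans (EHH, iHS, XP-EHH) with windowed outlier calling, region merging and
    gene/QTL annotation. Includes a forward-in-time Wright-Fisher simulator with
    selection, bottlenecks and sib-mating that generates phased multi-population
    fixtures with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
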