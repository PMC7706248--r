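Package: poolvaf
Title: Variant Allele Frequencies from Deep Pooled Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of deep pooled amplicon sequencing of heterogeneous,
    outcrossing germplasm accessions. Estimates within-accession variant
    allele frequencies (VAF) from pooled read counts or VCF allele depths,
    intersects multi-caller call sets, classifies coding effects against
    simple gene models, computes Nei's (1972) genetic distance from VAF
    matrices with neighbor-joining trees and principal coordinates analysis,
    tabulates private alleles by germplasm group, compares VAF distributions
    with a two-part Wilcoxon procedure for zero-inflated data, converts VAF
    to genotype-like scores under configurable thresholds, and designs and
    scores CAPS (cleaved amplified polymorphic sequence) validation assays.
    Includes a simulator of pooled accessions (96 diploid plants per pool,
    deep coverage, sequencing error, private and rare one-heterozygote
    alleles) so the whole pipeline is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
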