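Package: tetrasnp
Title: SNP Discovery and Diversity Analysis for Mixed-Ploidy Alfalfa Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-based SNP discovery and diversity analysis
    in panels mixing diploid and autotetraploid genotypes, as used in alfalfa
    (Medicago sativa) germplasm surveys. Implements a read-count filter cascade
    with a genotypic contingency test, ploidy-aware dosage-lumped genotype
    classification (AA/AB/BB), per-genotype and pooled-diploid heterozygosity,
    group polymorphism accounting (Venn regions), fixed-difference and
    candidate-contig scans, high-resolution-melting eligibility selection,
    simple-matching distances with neighbor-joining trees and principal
    components analysis, and a seeded synthetic panel generator with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
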