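Package: microkin
Title: Microhaplotype Panels for Forensic Kinship Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation of short microhaplotype panels for forensic
    paternity and sibling testing. Computes per-locus forensic parameters
    (effective number of alleles, observed heterozygosity, power of
    discrimination, probability of exclusion) and panel-wide combined
    powers; tests Hardy-Weinberg equilibrium by a Markov-chain exact test
    and pairwise linkage equilibrium by an EM-based permutation test;
    simulates genotype pairs under parent-child, full-sibling,
    half-sibling, first-cousin and unrelated hypotheses with
    locus-class-specific mutation models; computes kinship likelihood
    ratios (paternity index, full-, half- and full/half-sibling indices);
    and summarises system power as uncovered rates and thresholded
    decision metrics (sensitivity, specificity, predictive values, error
    rate, effectiveness). Ships a 36-locus panel definition and a
    29-locus Han Chinese allele-frequency table as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
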