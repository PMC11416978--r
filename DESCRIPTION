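Package: hladq
Title: HLA-DQ Genotype Interpretation for Coeliac Disease Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for HLA-based genetic testing in coeliac disease:
    parsing and normalisation of HLA-DQA1/DQB1 allele names, detection of
    the disease-predisposing DQ2.5, DQ2.2 and DQ8 heterodimers in unphased
    genotypes, three-category clinical interpretation under versioned
    national and international rule sets, haplotype-frequency and
    Hardy-Weinberg carrier arithmetic with Bayesian predictive values, and
    a seeded simulator and scorer for external proficiency testing (EPT)
    schemes, including method-stratified laboratory error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
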