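Package: dualcoloc
Title: Cross-Disease Colocalisation of GWAS Signals with Conditional
    Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genomic regions associated with two diseases from
    case-control GWAS data, dissects each region into conditionally
    independent association signals by forward stepwise logistic
    regression (with a COJO-style summary-statistic mode), tests every
    signal pair for Bayesian colocalisation via Wakefield approximate
    Bayes factors with full H0-H4 hypothesis enumeration, corroborates
    shared signals with an eCAVIAR-style colocalisation posterior
    probability (CLPP) from LD-aware fine-mapping, and classifies the
    direction of effect of shared signals as concordant or discordant.
    Includes a seeded generator of LD-structured haplotypes and
    two-trait case-control cohorts under a logistic disease model for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
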