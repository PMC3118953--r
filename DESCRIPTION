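Package: causalgwas
Title: Causal Graph-Based Analysis of Genome-Wide Association Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for multivariate causal graph-based analysis of
    case-control SNP genotype data. Provides quality-control filters (call
    rate, minor allele frequency, Hardy-Weinberg equilibrium), discrete G2
    conditional-independence testing with a sample-size reliability
    heuristic, Generalized Local Learning (GLL) Markov boundary induction
    and TIE* enumeration of all information-equivalent Markov boundaries of
    a binary phenotype, kernel ridge regression predictive signatures with
    nested cross-validation, hold-out and resampling evaluation with DeLong
    confidence intervals for the area under the ROC curve, and audits of
    missing-genotype patterns and of conditional independence of externally
    reported marker SNPs. Includes a synthetic genotype generator with
    planted causal structure, linkage disequilibrium, duplicate SNPs and
    configurable missingness so the whole pipeline is testable without
    access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
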