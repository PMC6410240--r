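Package: mtnadel
Title: Genotyping and Population Genetics of the MtnA 3' UTR Indel in
    Drosophila melanogaster
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the 49-bp insertion/deletion polymorphism in
    the 3' untranslated region of the Drosophila melanogaster Metallothionein A
    (MtnA) gene. Calls the deletion or non-deletion allele of sequenced fly
    lines from short reads with a dual-reference, junction-overlap,
    majority-fraction classifier; computes allele frequencies with exact and
    score confidence intervals, Hardy-Weinberg chi-squared and Levene-Haldane
    exact tests, and Fisher tests between collections; estimates relative
    expression from qPCR Ct tables by the delta-delta-Ct method with two-factor
    ANOVA; tests genotype-phenotype associations for expression and
    oxidative-stress survival (t test, Spearman correlation, Cox proportional
    hazards); and detects admixture with neighbor-joining trees and column
    bootstrap supports. A synthetic-data generator reproduces the statistical
    structure of every input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    withr,
    stats,
    utils,
    ape,
    survival,
    car,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
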