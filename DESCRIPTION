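Package: gpacc
Title: Deterministic Accuracy of Multi-Population Genomic Prediction with
    Multiple Genomic Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selection-index equations that predict the accuracy of within-
    and multi-population genomic prediction when one or two genomic
    relationship matrices (GRMs) are fitted, together with the machinery
    needed to apply and validate them: multi-population GRMs built with
    population-specific allele frequencies, estimation of the effective
    number of independent chromosome segments (Me) from GRM element
    variances, a two-population genotype and phenotype simulator with
    correlated causal effects, and a bivariate two-GRM GBLUP
    cross-validation harness that measures empirical accuracy against the
    deterministic predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
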