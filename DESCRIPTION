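Package: gebvalid
Title: Validation of Genomic Prediction Equations by Bivariate Pedigree REML
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for validating genomic prediction equations in pedigreed
    seed-stock populations. Prediction equations (per-SNP allele substitution
    effects) are trained by SNP-BLUP/GBLUP on designated training sets and
    applied to validation genotypes to obtain genomically estimated breeding
    values (GEBV). The accuracy of a GEBV is then estimated as the genetic
    correlation between the GEBV, modelled as a trait observation, and its
    phenotypic target trait in a bivariate animal model fitted by restricted
    maximum likelihood, with maternal genetic and maternal permanent
    environment effects for early weight traits. Includes pedigree utilities
    (numerator relationship matrix, sparse inverse, inbreeding), phenotype
    filtering rules, a multi-breed population simulator with known truth for
    parameter-recovery testing, and an orchestrator that replicates the
    across-breed study design on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, pracma, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
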