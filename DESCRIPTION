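Package: poetriad
Title: Parent-of-Origin Effects from Case-Parent Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and testing of parent-of-origin effects (POE) on a
    dichotomous disease from case-parent triads, using an
    ascertainment-conditional log-linear likelihood with maternally and
    paternally transmitted allele relative risks, optional double-dose and
    maternal-genotype terms, latent-transmission marginalization, and Wald
    inference on the maternal/paternal relative-risk ratio. Includes PLINK 1
    binary genotype input and output, triad assembly from pedigree structure,
    the standard per-sample and per-SNP quality-control filters (call rate,
    exact Hardy-Weinberg test on founders, minor allele frequency, Mendelian
    errors, heterozygosity outliers), environment-stratified fits with a POE
    by environment interaction contrast, Benjamini-Hochberg false discovery
    rate adjustment, gene and methylation-QTL annotation utilities, and a
    simulator of ascertained triads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
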