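Package: pahburden
Title: Rare-Variant Burden Discovery and Vasodilator-Response Analysis for
    Idiopathic Pulmonary Arterial Hypertension
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage rare-variant discovery and burden-association pipeline
    for idiopathic pulmonary arterial hypertension (IPAH) case-control
    studies: candidate-variant filtering under a dominant model (reference
    panel minor allele frequency, deleteriousness consensus, heterozygosity),
    gene-level aggregation with shared-carrier and tissue-expression
    prioritization, KING-robust pairwise kinship quality control, 2x2
    carrier-based association statistics (Wald odds ratios, logistic
    regression, continuity-corrected chi-square, Fisher exact), splice
    consequence arithmetic for donor-site variants (exon skipping, cryptic
    donor activation, HGVS protein deletion naming), and genotype-stratified
    acute-vasodilator response modelling (baseline-adjusted least-squares
    mean differences). A seeded synthetic cohort generator reproduces the
    statistical structure the analysis assumes, so the full pipeline is
    testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans
Config/testthat/edition: 3
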