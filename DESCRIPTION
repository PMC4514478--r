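Package: maburden
Title: Minor-Allele Burden Analysis and Weighted Risk Prediction for
    Case/Control Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide minor-allele burden analysis in
    case/control cohorts genotyped on SNP arrays. Determines minor alleles
    from control allele frequencies, computes the per-individual minor
    allele content (MAC), fits per-SNP logistic association models, and
    builds weighted minor-allele risk scores in which heterozygotes
    contribute half a coefficient. Includes PLINK text (PED/MAP,
    TPED/TFAM) input/output, sample and variant quality control
    (Hardy-Weinberg exact test, missingness and MAF filters, genetic
    relationship matrix PCA with outlier exclusion, duplicate removal),
    linkage-disequilibrium block construction with representative SNP
    selection, ROC/AUC and true-positive-rate-at-full-specificity
    evaluation with confidence intervals, stratified k-fold and external
    cross-cohort validation, and a synthetic cohort generator with an
    additive minor-allele disease model for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
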