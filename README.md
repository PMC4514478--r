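# maburden

Minor-allele burden analysis and weighted minor-allele risk prediction for
case/control SNP-array cohorts.

## The scientific problem

Most risk alleles found by case/control GWAS are minor alleles (MAs), and a
long-standing hypothesis holds that the *collective* load of minor alleles —
not any single locus — contributes to complex disease: too many mildly
deleterious variants may push an individual past a tolerance threshold.
`maburden` implements the two quantities this idea leads to, together with
everything needed to evaluate them honestly:

- **Minor allele content (MAC)** — a per-individual burden statistic. With
  the minor allele of each SNP oriented by its frequency in the *control*
  population, an individual's MAC is

  MAC = (number of minor-allele copies carried) / (2 × number of called
  informative SNPs),

  a per-allele proportion in [0, 1]. SNPs with control MAF exactly 0.5, or
  with the minor allele absent from both groups, are non-informative and
  excluded; missing genotypes drop out of numerator and denominator. Case
  and control mean MAC are compared by one-way ANOVA.

- **Weighted MA risk score** — for each SNP passing the selection criteria
  (control MAF < 0.4, per-SNP logistic association p < 0.05, minor allele
  more frequent in cases), the weight is the fitted logistic coefficient
  β of case status on minor-allele copies. An individual's score is

  S = Σ_j β_j · g_j / 2,   g_j ∈ {0, 1, 2},

  so a heterozygote contributes β/2 and a minor-allele homozygote β.
  Discrimination is measured by the ROC AUC (DeLong 95% CI) and by the TPR
  at 100% specificity — the fraction of cases scoring strictly above every
  control — with an exact binomial CI. Because thousands of marginally
  selected SNPs are combined, in-sample scores separate cases from controls
  almost perfectly while honest held-out performance is far lower; the
  package therefore ships internal stratified k-fold and external
  cross-cohort validation (with panel intersection, strand reconciliation
  and model reduction) as first-class operations, plus a synthetic cohort
  generator with known ground truth for calibration and parameter-recovery
  studies.

The supporting cast: PLINK text I/O (PED/MAP, TPED/TFAM), QC filters (exact
Hardy–Weinberg test in controls, missingness > 5%, MAF < 1e-4, GRM-based
ancestry PCA with outlier exclusion, duplicate removal), LD blocks within
200 kb summarized by a best-association representative SNP, a six-model ×
p-threshold comparison sweep, and a config-driven `run_pipeline()`.

## Worked example

Simulate a pair of 500-case / 500-control cohorts (5,000 SNPs, 100 weak
risk SNPs) from one generative truth, train the standard model on one and
validate on the other:

```r
library(maburden)

cfg <- sim_config(n_cases = 500, n_controls = 500, n_snps = 5000,
                  n_risk_snps = 100,
                  effect_size_spec = list(mean = 0.5, sd = 0.1, sign = "positive"),
                  baseline_log_odds = -10, seed = 42)
pair <- simulate_cohort_pair(cfg, cfg, snp_overlap_fraction = 1)

fit <- ma_risk(pair$a$cohort)        # MAF < 0.4, p < 0.05, cases-enriched
summary(fit)
#> Weighted minor-allele risk model (ma_risk)
#>   145 SNPs selected (control MAF < 0.4, p < 0.05, direction: cases_enriched)
#>   trained on 500 cases / 500 controls (training)
#>   training score means: cases 7.563, controls 5.783
#>   in-sample AUC 0.905 (95% CI 0.887-0.923)  [optimistic: same data used to select and weight SNPs]
#>   in-sample TPR at 100% specificity 0.206 (95% CI 0.171-0.244)

external_validate(pair$a$cohort, pair$b$cohort, model = fit)$report
#> evaluation_report: 500 cases vs 500 controls
#>   AUC 0.6053 (95% CI 0.5705-0.6401)
#>   TPR at 100% specificity 0.0060 (95% CI 0.0012-0.0174), threshold 9.511

mac <- compute_mac(pair$a$cohort, compute_control_maf(pair$a$cohort))
compare_group_means(split(mac$mac, mac$phenotype))
#> MAC one-way ANOVA: F = 4.24, p = 0.0398

kfold_cross_validate(pair$a$cohort, k = 10, seed = 42)
#> 10-fold cross-validation (seed 42)
#>   mean AUC 0.5767, mean TPR at 100% specificity 0.0160
```

Reading the numbers: cases carry a measurably higher minor-allele burden
(ANOVA p ≈ 0.04); the trained 145-SNP score looks spectacular in-sample
(AUC 0.905) but honest external validation yields AUC 0.61 and detects
0.6% of cases with zero false positives — the overfitting gap the
validation machinery exists to expose. The 10-fold CV (every sample
validated exactly once, minor-allele orientation and weights re-derived
inside each training split) tells the same story.

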