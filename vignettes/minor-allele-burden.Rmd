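---
title: "Minor-allele burden and weighted risk scores: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minor-allele burden and weighted risk scores: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maburden)
```

# The model and its assumptions

`maburden` analyses case/control cohorts of biallelic autosomal SNPs under
a simple, deliberately transparent model of collective minor-allele
effects.

**Minor-allele orientation.** The minor allele (MA) of every SNP is the
allele that is less frequent among the *controls*. Orienting by controls
rather than by the pooled sample keeps the definition independent of case
enrichment, which is the very signal under study. Three situations make a
SNP unusable for burden analysis and flag it non-informative: control MAF
exactly 0.5 (orientation is arbitrary), minor allele absent from cases and
controls alike (nothing to count), and no called control genotypes
(nothing to orient by).

**Minor allele content (MAC).** An individual's MAC is their count of MA
copies at informative, called SNPs divided by the number of allele slots
assayed there (2 × called SNPs). This is a per-allele proportion in
[0, 1]. The phrase "divided by the number of SNPs scanned" is ambiguous
between per-SNP and per-allele scaling; we use the per-allele denominator
because it bounds MAC by 1 and the choice only rescales everything by 2 —
group comparisons (one-way ANOVA via `stats::aov`) are invariant to it.

**Per-SNP association weights.** Each SNP gets a logistic regression of
case status on MA copy count (0/1/2) with an intercept, fitted by
Newton/IRLS to a coefficient-change tolerance of 1e-8 within 50
iterations. The fits are vectorized across SNPs (all per-iteration sums
are column operations on the samples × SNPs dosage matrix), which is what
makes fold-wise refitting in cross-validation affordable. Non-converged
fits, separated fits (|β| ≥ 15 or exploding standard errors) and constant
genotypes are flagged and excluded from models rather than clamped: a
clamped coefficient would silently dominate every score it enters.
P-values are Wald. No covariates are included by default — an adjusted
analysis (e.g. for sex, given the strong imbalance typical of these
cohorts) changes the weights' meaning and is left to the user.

**The risk model.** `ma_risk()` selects SNPs with control MAF strictly
below a ceiling (default 0.4 — SNPs between 0.4 and 0.5 are excluded
because their MA status is least certain), association p strictly below a
threshold (default 0.05), and, by default, MA frequency higher in cases
than controls (the *direction* filter; configurable off, since a sweep
over thresholds may legitimately want both directions). The weight is the
logistic coefficient; the score of an individual is Σ β·g/2, so
heterozygotes contribute half a coefficient. Missing genotypes contribute
zero and decrement the per-sample used-SNP count; no mean imputation and
no per-sample renormalization are applied, because the external-validation
design this package supports deliberately tolerates heavy panel reduction
without reweighting. A normalized per-used-SNP column is provided for
users who want it.

**Evaluation.** AUC is the rank-sum (pair-counting) estimator with ties
counted half, with a DeLong structural-components 95% CI; the ROC curve is
built from the "positive iff score ≥ threshold" rule at every distinct
score, which makes its trapezoid area equal the rank-sum AUC *exactly* (a
tested identity). TPR at 100% specificity is the fraction of cases
*strictly* above the maximum control score — a tie with the top control is
not a detection — with a Clopper–Pearson exact CI (`stats::binom.test`);
the asymmetric intervals suit a proportion that is typically a few
percent. AUC and TPR are invariant under any strictly increasing
transformation of scores.

# Validation designs

**External (cross-cohort) validation** trains wholly on one cohort —
including MA orientation, from the training controls — reduces the model
to the SNPs present on the test panel (`reduce_model_to_panel()`, with the
retained fraction logged) and scores the test cohort. Allele matching at
scoring time accepts identity or strand complement; A/T and C/G SNPs
cannot be disambiguated by complement matching and are dropped at panel
intersection by default (`drop_ambiguous = TRUE`; disable only for cohorts
known to share a strand convention).

**Internal k-fold cross-validation** stratifies folds by case status so
every fold holds both classes, and re-derives the *entire* pipeline — MA
set, weights, selection — inside each training split. Whether published
analyses re-estimated weights per fold is usually unstated; the no-leakage
choice is the only defensible default, and it is the one implemented.
Every sample is validated exactly once; per-fold AUC/TPR are averaged.

**The model sweep** compares six model families — five control-MAF
ceilings {0.1, 0.2, 0.3, 0.4, 0.5} and one haplotype model — across a
p-threshold grid (default {1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5}; the
grid actually used in published figures is rarely printed, so both axes
are configuration). Association fits and LD blocks are computed once per
sweep.

**Haplotype model.** SNPs are grouped into LD blocks by greedy
left-to-right agglomeration: a SNP joins the open block iff it lies within
200 kb of the block start and its maximum genotype r² with current members
reaches 0.5 (both configurable); otherwise a new block opens. Every SNP
belongs to exactly one block, singletons allowed, and spans never exceed
the window. LD is measured as composite genotype r² — the squared Pearson
correlation of copy counts — rather than EM-phased haplotype r²: the
genotype measure is deterministic, phase-free, and a standard proxy; this
is an approximation, documented as such. Each block is represented by its
smallest-p member among those meeting the MAF/p criteria (marginal per-SNP
p-values are used for "best disease linkage"; a joint within-block
regression is a different estimand and was deliberately not chosen), ties
broken toward the smaller bp position. Blocks with no qualifying member
contribute nothing. Published block *counts* are not targeted — they
depend on LD structure of data this package does not possess.

# Quality control

Applied in a fixed, recorded order: exact duplicates (genotype concordance
≥ 0.99 on up to 10,000 SNPs; the later sample of a pair is dropped,
deterministically), ancestry-PCA outliers, missingness/MAF, HWE.

- The Hardy–Weinberg test is the conditional *exact* test (full
  enumeration of the heterozygote distribution given allele counts; the
  p-value sums probabilities of tables no more probable than the observed
  one). The exact test does not break down at small counts the way the
  chi-square does. It is applied in controls only by default — true
  association distorts HWE in cases — at p ≤ 0.01.
- Missingness > 5% and control MAF < 1e-4 are strict thresholds: a SNP at
  exactly 5% missing is retained.
- Ancestry PCs come from the eigendecomposition of the genetic
  relationship matrix built from frequency-standardized genotypes,
  (g − 2p)/√(2p(1−p)), averaged over jointly non-missing SNPs. Samples
  beyond 6 SD (configurable; published criteria are usually unstated, so
  the multiplier is an explicit knob, not a guess presented as fact) on
  any of PC1–3 are excluded in a single pass.

# The synthetic cohort generator

`simulate_cohort()` draws population MAFs from a Beta(1, 2.2) spectrum
rescaled to [0.01, 0.5] — right-skewed toward low frequencies, as on
genotyping arrays after rare-variant attrition — genotypes in
Hardy–Weinberg proportions given frequency, and case status from a
logistic model on Σ effect × copies/2. Effects live on the same dosage
scale as the scoring rule, so recovered coefficients are directly
comparable to generative effects. Default effects are Normal(0.05, 0.02)
forced positive across 50 of 5,000 SNPs: the effect-size distribution
behind real selected-SNP sets is uncharacterized, so these defaults are
explicit configuration, not estimates. Cases and controls are filled by
rejection sampling from a virtual population (cap: 100 × the requested
total, then an explicit failure), which preserves HWE in controls without
retrospective-likelihood machinery; `baseline_log_odds = 0` corresponds to
a balanced design where prevalence is not modelled. Missingness masks each
genotype independently. Positions are laid down with ~20 kb mean spacing
on 22 synthetic autosomes so the 200 kb window is exercisable.

Beyond Hardy–Weinberg, SNPs are independent by default. An optional
block-copula mode makes each haplotype carry one latent allele per block
of adjacent SNPs (frequency: the block head's MAF), copied by every member
with an independent flip probability — producing high within-block r²
while each SNP marginally remains a Hardy–Weinberg draw; the truth table
records the flip-adjusted marginal frequency. `simulate_cohort_pair()`
draws two cohorts from one truth with an exact count of shared SNP ids,
and disease status always depends on the full risk-SNP set whether or not
a risk SNP is on a given cohort's panel — as in reality, where a disease
does not care which array a cohort was genotyped on.

What the generator does *not* emulate: realistic recombination maps and LD
decay, population structure and admixture, genotyping error, batch
effects, and the empirical effect-size distribution of any real disease.
Passing calibration and recovery tests on these simulations therefore
demonstrates that the *machinery* is correct and unbiased — not that any
particular real-data result is right.

# Numerical and policy choices

- Strict inequalities throughout the selection and detection rules
  (MAF < ceiling, p < threshold, score > threshold): a case tied with the
  best control is not detected.
- Degenerate ANOVA input (zero within-group variance) is answered by
  convention — F = 0, p = 1 for equal means — rather than passed to a
  numerically unstable computation.
- Duplicate removal keeps the earlier sample; representative-SNP ties go
  to the smaller position; both make reruns byte-identical.
- All stochastic steps (simulation, fold assignment) flow from explicit
  integer seeds; `run_pipeline()` echoes its configuration verbatim, logs
  the config hash and seed, and two runs differing only in output path
  produce identical tables.

# Problem sizes used by the test suite

The suite validates calibration and recovery at sizes a laptop handles
comfortably, chosen as the package's standard desk-scale study: null
calibration on twenty 1000+1000 × 2000-SNP cohort pairs; parameter
recovery on twenty 1000/1000-training, 600/300-test pairs with 50 planted
risk SNPs (dosage log-odds 0.2) among 5,000; the in-sample/held-out
overfitting contrast at 100+100 samples × 20,000 SNPs, where selection at
p < 0.05 yields several hundred weighted SNPs against 200 individuals;
and an end-to-end pipeline run (sweep, 10-fold CV, external validation
through a 24% panel intersection) at 500/500 × 5,000. Real GWAS are two
to three orders of magnitude larger in SNP count; every algorithm here is
linear in SNPs except duplicate detection and the GRM (quadratic in
samples, computed via BLAS cross-products and capped at 10,000 SNPs).

# Known limitations

- Genotype r² understates phased haplotype r² when phase matters; block
  boundaries are greedy, not confidence-interval based (Gabriel-style),
  so blocks differ from PLINK's in detail while serving the same
  downstream contract (one representative per block).
- The logistic fits are marginal per SNP: LD between selected SNPs
  double-counts shared signal in the score. No shrinkage or joint
  modelling is applied — by design, to keep the score definition
  faithful — so scores are not calibrated probabilities.
- MA orientation from finite control samples is noisy near MAF 0.5;
  the 0.4 ceiling exists precisely to keep orientation reliable.
- The absolute score threshold achieving 100% specificity is meaningful
  only relative to a fixed model and panel; it does not transfer across
  panel reductions without re-evaluation.
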