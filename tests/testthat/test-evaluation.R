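test_that("rank-sum AUC matches brute-force pair counting", {
  set.seed(41)
  for (i in 1:30) {
    cs <- round(rnorm(sample(2:25, 1)), 1)   # rounding forces ties
    ct <- round(rnorm(sample(2:25, 1)), 1)
    expect_equal(auc_delong(cs, ct)$auc, auc_pair_oracle(cs, ct),
                 tolerance = 1e-12)
  }
  expect_equal(auc_delong(c(2, 0), 1)$auc, 0.5)
  # complement symmetry
  cs <- rnorm(40); ct <- rnorm(30)
  expect_equal(auc_delong(cs, ct)$auc, 1 - auc_delong(ct, cs)$auc)
})

test_that("DeLong intervals agree with an independent implementation", {
  set.seed(43)
  for (i in 1:5) {
    cs <- rnorm(60, mean = 0.5); ct <- rnorm(80)
    mine <- auc_delong(cs, ct)
    r <- pROC::roc(c(rep(1, 60), rep(0, 80)), c(cs, ct), quiet = TRUE)
    ci <- pROC::ci.auc(r, method = "delong")
    expect_equal(mine$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
    expect_equal(mine$ci, as.numeric(ci[c(1, 3)]), tolerance = 1e-9)
  }
})

test_that("TPR at 100% specificity counts strictly-above cases", {
  t <- tpr_full_specificity(c(3, 2, 1), c(2, 1))
  expect_equal(t$tpr, 1 / 3)
  expect_equal(t$threshold, 2)
  expect_equal(t$n_detected, 1L)
  expect_equal(t$ci, as.numeric(binom.test(1, 3)$conf.int))
  expect_equal(tpr_full_specificity(c(1, 2), c(5, 2))$tpr, 0)
  # a case tied with the top control is not detected
  expect_equal(tpr_full_specificity(c(2, 2), c(2, 0))$tpr, 0)
})

test_that("ROC curves are monotone and integrate to the rank-sum AUC", {
  set.seed(47)
  for (i in 1:50) {
    cs <- round(rnorm(sample(2:40, 1)), 1)
    ct <- round(rnorm(sample(2:40, 1)), 1)
    rc <- roc_curve(cs, ct)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
    expect_equal(maburden:::trapezoid_auc(rc), auc_delong(cs, ct)$auc,
                 tolerance = 1e-12)
  }
  # perfect separation passes through (0, 1)
  rc <- roc_curve(c(5, 6), c(1, 2))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  # TPR at full specificity is the ROC's TPR at FPR = 0
  cs <- rnorm(50, 1); ct <- rnorm(50)
  rc <- roc_curve(cs, ct)
  expect_equal(max(rc$tpr[rc$fpr == 0]), tpr_full_specificity(cs, ct)$tpr)
})

test_that("evaluation report assembles consistent pieces", {
  set.seed(49)
  ev <- evaluate_scores(rnorm(40, 1), rnorm(60))
  expect_s3_class(ev, "evaluation_report")
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_true(all(ev$auc_ci >= 0 & ev$auc_ci <= 1))
  # at the reported threshold no control is predicted-case
  ct <- rnorm(60)
  ev2 <- evaluate_scores(rnorm(40, 1), ct)
  expect_equal(sum(ct > ev2$threshold), 0)
  expect_output(print(ev), "AUC")
})

test_that("stratified k-fold CV partitions samples and averages folds", {
  sim <- quick_sim(seed = 51, n_cases = 60, n_controls = 60, n_snps = 150,
                   n_risk = 20, effect = 0.4)
  cv <- kfold_cross_validate(sim$cohort, k = 5, seed = 3)
  expect_equal(sort(unique(cv$assignment)), 1:5)
  expect_equal(length(cv$assignment), 120L)
  expect_equal(sum(cv$folds$n_test), 120L)      # each sample exactly once
  expect_equal(cv$mean_auc, mean(cv$folds$auc))
  expect_equal(cv$mean_tpr, mean(cv$folds$tpr))
  # every fold held both classes (metrics exist)
  expect_true(all(is.finite(cv$folds$auc)))
  # deterministic under the same seed
  cv2 <- kfold_cross_validate(sim$cohort, k = 5, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cross_validate(sim$cohort[1:12, ], k = 10), "stratified")
})

test_that("external validation trains only on the training cohort", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_snps = 400,
                    n_risk_snps = 60,
                    effect_size_spec = list(mean = 0.6, sd = 0.05,
                                            sign = "positive"),
                    missing_rate = 0.01, seed = 53)
  pair <- simulate_cohort_pair(cfg, cfg, snp_overlap_fraction = 1)
  ev <- external_validate(pair$a$cohort, pair$b$cohort)
  # full overlap: identical to scoring the test cohort directly
  mod <- ma_risk(pair$a$cohort)
  direct <- score_individuals(mod, pair$b$cohort)
  expect_equal(ev$scores$score, direct$score)
  # training-set evaluation is optimistic relative to external
  in_auc <- summary(mod)$in_sample_auc
  expect_gt(in_auc, ev$report$auc)
  expect_gt(ev$report$auc, 0.5)
})

test_that("the model sweep covers six models across the p grid", {
  cfg <- sim_config(n_cases = 80, n_controls = 80, n_snps = 300,
                    n_risk_snps = 30,
                    effect_size_spec = list(mean = 0.4, sd = 0.05,
                                            sign = "positive"),
                    missing_rate = 0, seed = 57)
  pair <- simulate_cohort_pair(cfg, cfg, snp_overlap_fraction = 1)
  p_grid <- c(0.05, 0.5, 1)
  sw <- model_sweep(pair$a$cohort, pair$b$cohort, p_grid = p_grid)
  expect_equal(nrow(sw), 6L * length(p_grid))
  expect_setequal(unique(sw$model),
                  c("maf<0.1", "maf<0.2", "maf<0.3", "maf<0.4", "maf<0.5",
                    "haplotype"))
  # a vacuous p threshold selects every qualifying SNP
  assoc <- snp_association(pair$a$cohort)
  expect_equal(sw$n_snps[sw$model == "maf<0.5" & sw$p_threshold == 1],
               nrow(maburden:::select_model_snps(assoc, 0.5, 1)))
  # model sizes grow with the p threshold
  s4 <- sw[sw$model == "maf<0.4", ]
  expect_true(all(diff(s4$n_snps[order(s4$p_threshold)]) >= 0))
})

test_that("control-population validation pools and stays monotone", {
  cfg <- sim_config(n_cases = 80, n_controls = 80, n_snps = 300,
                    n_risk_snps = 30,
                    effect_size_spec = list(mean = 0.4, sd = 0.05,
                                            sign = "positive"),
                    missing_rate = 0, seed = 59)
  ctrl_cfg <- sim_config(n_cases = 0, n_controls = 150, n_snps = 300,
                         missing_rate = 0, seed = 60)
  pair <- simulate_cohort_pair(cfg, ctrl_cfg, snp_overlap_fraction = 0.5)
  expect_length(pair$shared_snp_ids, 150L)
  model <- ma_risk(pair$a$cohort, p_threshold = 0.3)
  red <- reduce_model_to_panel(model, pair$b$cohort$variants$snp_id)
  case_scores <- with(score_individuals(red, pair$a$cohort),
                      score[phenotype == "case"])
  v1 <- control_only_validation(model, pair$b$cohort, case_scores)
  expect_true(v1$tpr >= 0 && v1$tpr <= 1)
  # pooling extra high-scoring controls can only lower the detected fraction
  v2 <- control_only_validation(model, pair$b$cohort, case_scores,
                                extra_control_scores = max(case_scores))
  expect_lte(v2$tpr, v1$tpr)
  disjoint <- pair$b$cohort
  disjoint$variants$snp_id <- paste0("x", disjoint$variants$snp_id)
  expect_error(control_only_validation(model, disjoint, case_scores),
               "intersection")
})
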