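make_fitted_model <- function(seed = 23) {
  sim <- quick_sim(seed = seed, n_cases = 120, n_controls = 120, n_snps = 250,
                   n_risk = 25, effect = 0.4, missing_rate = 0.02)
  list(sim = sim, model = ma_risk(sim$cohort))
}

test_that("selection criteria are strict and echoed on failure", {
  fx <- make_fitted_model()
  assoc <- fx$model$association
  # vacuous criteria select every informative converged SNP
  all_mod <- ma_risk(fx$sim$cohort, maf_ceiling = 0.51, p_threshold = 1.01,
                     direction = "any", association = assoc,
                     ma_set = fx$model$ma_set)
  expect_equal(nrow(all_mod$snps),
               sum(assoc$informative & assoc$converged))
  # every selected SNP satisfies all criteria
  sn <- fx$model$snps
  expect_true(all(sn$control_maf < 0.4))
  expect_true(all(sn$p_value < 0.05))
  cm <- assoc$case_maf[match(sn$snp_id, assoc$snp_id)]
  expect_true(all(cm > sn$control_maf))
  # a SNP at control MAF 0.45 is excluded at ceiling 0.4
  high <- assoc$snp_id[!is.na(assoc$control_maf) & assoc$control_maf > 0.4]
  expect_false(any(high %in% sn$snp_id))
  expect_error(ma_risk(fx$sim$cohort, p_threshold = 1e-30),
               "no SNP meets the selection criteria")
})

test_that("scoring follows the half-weight heterozygote rule", {
  fx <- make_fitted_model()
  model <- fx$model
  snp1 <- model$snps$snp_id[1]
  w <- model$snps$weight[1]
  gm <- fx$sim$cohort[1:3, model$snps$snp_id]
  # construct genotypes by hand: hom-minor / het / hom-major at snp1,
  # hom-major elsewhere (counted allele is the minor allele here)
  ori <- ifelse(model$snps$minor_allele == gm$variants$counted, 0L, 2L)
  gm$calls <- matrix(rep(ori, each = 3), 3, nrow(model$snps))
  dimnames(gm$calls) <- list(gm$samples$sample_id, gm$variants$snp_id)
  gm$calls[1, 1] <- 2L - ori[1]          # hom-minor
  gm$calls[2, 1] <- 1L                   # het
  sc <- score_individuals(model, gm)
  expect_equal(sc$score, c(w, 0.5 * w, 0))
  expect_equal(sc$n_used, rep(nrow(model$snps), 3L))
  # a missing call contributes zero and decrements the used count
  gm$calls[1, 2] <- NA
  sc2 <- score_individuals(model, gm)
  expect_equal(sc2$score[1], w)
  expect_equal(sc2$n_used[1], nrow(model$snps) - 1L)
})

test_that("scores are additive over disjoint SNP sets and homogeneous", {
  fx <- make_fitted_model()
  model <- fx$model
  gm <- fx$sim$cohort
  half <- nrow(model$snps) %/% 2
  mA <- model; mA$snps <- model$snps[seq_len(half), ]
  mB <- model; mB$snps <- model$snps[-seq_len(half), ]
  sA <- score_individuals(mA, gm)$score
  sB <- score_individuals(mB, gm)$score
  sAll <- score_individuals(model, gm)$score
  expect_equal(sA + sB, sAll, tolerance = 1e-12)
  m2 <- model; m2$snps$weight <- 2 * model$snps$weight
  expect_equal(score_individuals(m2, gm)$score, 2 * sAll, tolerance = 1e-12)
  # AUC is invariant under strictly increasing transforms of the scores
  phen <- gm$samples$phenotype
  a1 <- auc_delong(sAll[phen == "case"], sAll[phen == "control"])$auc
  tr <- exp(sAll / 2)
  a2 <- auc_delong(tr[phen == "case"], tr[phen == "control"])$auc
  expect_equal(a1, a2)
})

test_that("panel reduction keeps the intersection and its score signal", {
  fx <- make_fitted_model()
  model <- fx$model
  gm <- fx$sim$cohort
  expect_identical(reduce_model_to_panel(model, gm$variants$snp_id)$snps,
                   model$snps)
  keep <- model$snps$snp_id[seq_len(ceiling(nrow(model$snps) / 4))]
  red <- reduce_model_to_panel(model, keep)
  expect_equal(nrow(red$snps), length(keep))
  expect_equal(red$reduction$fraction_kept,
               length(keep) / nrow(model$snps))
  expect_error(reduce_model_to_panel(model, "nonexistent"), "intersection")
  # reduced-panel scores stay positively correlated with full scores
  s_full <- score_individuals(model, gm)$score
  s_red <- score_individuals(red, gm)$score
  expect_gt(cor(s_full, s_red), 0.3)
})

test_that("threshold classification uses a strict inequality", {
  sc <- structure(data.frame(sample_id = c("a", "b", "c"),
                             phenotype = c("case", "case", "control"),
                             score = c(2, 1, 1)),
                  class = c("score_profile", "data.frame"))
  expect_identical(threshold_classify(sc, 1),
                   c("predicted-case", "predicted-control",
                     "predicted-control"))
  expect_identical(unique(threshold_classify(sc, -Inf)), "predicted-case")
  # max-control threshold reproduces the TPR-at-100%-specificity labels
  lab <- threshold_classify(sc, max(sc$score[sc$phenotype == "control"]))
  tpr <- tpr_full_specificity(sc$score[sc$phenotype == "case"],
                              sc$score[sc$phenotype == "control"])
  expect_equal(mean(lab[sc$phenotype == "case"] == "predicted-case"), tpr$tpr)
})

test_that("model methods expose the usual fitted-model surface", {
  fx <- make_fitted_model()
  model <- fx$model
  expect_output(print(model), "Weighted minor-allele risk model")
  expect_named(coef(model), model$snps$snp_id)
  sm <- summary(model)
  expect_s3_class(sm, "summary.ma_risk")
  expect_gt(sm$in_sample_auc, 0.5)
  expect_identical(predict(model)$score, model$train_scores$score)
  lab <- predict(model, fx$sim$cohort, type = "class", threshold = Inf)
  expect_identical(unique(lab), "predicted-control")
  sims <- simulate(model, nsim = 2, seed = 99, n_cases = 30, n_controls = 30)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), c(60L, nrow(model$snps)))
})
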