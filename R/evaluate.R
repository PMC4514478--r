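#' Area under the ROC curve with DeLong confidence interval
#'
#' Rank-sum (pair-counting) AUC: the probability that a random case
#' outscores a random control, with ties counted half. The 95% CI uses
#' the DeLong structural-components variance estimator, clipped to
#' \[0, 1\].
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return List with `auc`, `ci` (length 2) and `se`.
#' @export
auc_delong <- function(case_scores, control_scores) {
  m <- length(case_scores)
  n <- length(control_scores)
  if (m < 1L || n < 1L) stop("need at least one case and one control score")
  r_all <- rank(c(case_scores, control_scores))
  r_case <- rank(case_scores)
  r_ctrl <- rank(control_scores)
  v10 <- (r_all[seq_len(m)] - r_case) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  s <- 0
  if (m > 1L) s <- s + stats::var(v10) / m
  if (n > 1L) s <- s + stats::var(v01) / n
  se <- sqrt(s)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
  list(auc = auc, ci = ci, se = se)
}

#' True positive rate at 100% specificity
#'
#' The fraction of cases scoring strictly above the highest control
#' score, i.e. the sensitivity achievable with zero false positives. A
#' case tied with the maximum control does not count as detected. The
#' 95% CI is exact binomial (Clopper-Pearson).
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return List with `tpr`, `ci` (length 2), `threshold` (the maximum
#'   control score), `n_detected` and `n_cases`.
#' @export
tpr_full_specificity <- function(case_scores, control_scores) {
  if (!length(case_scores) || !length(control_scores))
    stop("need at least one case and one control score")
  thr <- max(control_scores)
  k <- sum(case_scores > thr)
  m <- length(case_scores)
  ci <- as.numeric(stats::binom.test(k, m)$conf.int)
  list(tpr = k / m, ci = ci, threshold = thr, n_detected = k, n_cases = m)
}

#' ROC curve points
#'
#' One point per distinct score (classification rule: positive iff score
#' >= threshold), plus the (0, 0) origin; monotone non-decreasing in both
#' axes, ending at (1, 1). The trapezoid area of this curve equals the
#' rank-sum AUC of [auc_delong()] exactly.
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return Data frame with `threshold` (`Inf` at the origin), `fpr`,
#'   `tpr`.
#' @export
roc_curve <- function(case_scores, control_scores) {
  if (!length(case_scores) || !length(control_scores))
    stop("need at least one case and one control score")
  thr <- sort(unique(c(case_scores, control_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(case_scores >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(control_scores >= t), numeric(1L))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

## trapezoid area under a roc_curve data frame
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Full discrimination report for a set of scores
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return An object of class `evaluation_report`: ROC points, AUC with
#'   95% CI, TPR at 100% specificity with 95% CI, the zero-false-positive
#'   threshold, and group sizes.
#' @export
evaluate_scores <- function(case_scores, control_scores) {
  a <- auc_delong(case_scores, control_scores)
  t <- tpr_full_specificity(case_scores, control_scores)
  structure(list(roc = roc_curve(case_scores, control_scores),
                 auc = a$auc, auc_ci = a$ci,
                 tpr = t$tpr, tpr_ci = t$ci, threshold = t$threshold,
                 n_cases = length(case_scores),
                 n_controls = length(control_scores)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$n_cases, "cases vs", x$n_controls, "controls\n")
  cat(sprintf("  AUC %.4f (95%% CI %.4f-%.4f)\n", x$auc, x$auc_ci[1L],
              x$auc_ci[2L]))
  cat(sprintf("  TPR at 100%% specificity %.4f (95%% CI %.4f-%.4f), threshold %.4g\n",
              x$tpr, x$tpr_ci[1L], x$tpr_ci[2L], x$threshold))
  invisible(x)
}

#' @export
plot.evaluation_report <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

split_scores <- function(sc) {
  list(case = sc$score[sc$phenotype %in% "case"],
       ctrl = sc$score[sc$phenotype %in% "control"])
}

#' External (cross-cohort) validation of a risk model
#'
#' Trains a risk model wholly on one cohort (minor-allele orientation
#' from the training controls), reduces it to the SNPs available on the
#' test cohort's panel, scores the test cohort and reports its
#' discrimination.
#'
#' @param train,test [genotype_matrix()] cohorts; panels may differ.
#' @param maf_ceiling,p_threshold,direction Model criteria, as in
#'   [ma_risk()].
#' @param model Optional pre-fitted [ma_risk()] model (skips training).
#' @return List with `report` (an `evaluation_report` on the test
#'   cohort), `model` (the reduced model) and `scores` (test
#'   `score_profile`).
#' @export
external_validate <- function(train, test, maf_ceiling = 0.4,
                              p_threshold = 0.05,
                              direction = "cases_enriched", model = NULL) {
  if (is.null(model))
    model <- ma_risk(train, maf_ceiling, p_threshold, direction)
  model <- reduce_model_to_panel(model, test$variants$snp_id)
  sc <- score_individuals(model, test)
  s <- split_scores(sc)
  list(report = evaluate_scores(s$case, s$ctrl), model = model, scores = sc)
}

#' Six-model discrimination sweep over p-value thresholds
#'
#' Reproduces the model-comparison design: five models defined by
#' control-MAF ceilings plus one haplotype model (LD-block
#' representative SNPs), each trained on the training cohort at every
#' p-value threshold in the grid and evaluated on the test cohort.
#' Association fits and LD blocks are computed once and reused.
#'
#' @param train,test [genotype_matrix()] cohorts.
#' @param maf_ceilings Numeric vector of control-MAF ceilings.
#' @param p_grid Numeric vector of association p-value thresholds.
#' @param include_haplotype Add the haplotype-representative model
#'   (selection criteria MAF < 0.4, p < threshold, within blocks).
#' @param direction As in [ma_risk()].
#' @param window_bp,r2_min LD-block parameters for the haplotype model.
#' @return A `sweep_result` data frame, one row per model x threshold:
#'   `model`, `maf_ceiling`, `p_threshold`, `n_snps`, `auc`, `tpr`
#'   (`NA` metrics for empty cells).
#' @export
model_sweep <- function(train, test, maf_ceilings = c(0.1, 0.2, 0.3, 0.4, 0.5),
                        p_grid = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5),
                        include_haplotype = TRUE,
                        direction = "cases_enriched",
                        window_bp = 200000, r2_min = 0.5) {
  ma_set <- compute_control_maf(train)
  assoc <- snp_association(train, ma_set)
  blocks <- if (include_haplotype) build_blocks(train, window_bp, r2_min)
  rows <- list()
  cells <- expand.grid(ceiling = maf_ceilings, p = p_grid,
                       KEEP.OUT.ATTRS = FALSE)
  eval_cell <- function(snps, label, ceiling, p) {
    if (nrow(snps) == 0L)
      return(data.frame(model = label, maf_ceiling = ceiling,
                        p_threshold = p, n_snps = 0L,
                        auc = NA_real_, tpr = NA_real_))
    mod <- structure(list(snps = snps,
                          criteria = list(maf_ceiling = ceiling,
                                          p_threshold = p,
                                          direction = direction)),
                     class = "ma_risk")
    tryCatch({
      mod <- reduce_model_to_panel(mod, test$variants$snp_id)
      s <- split_scores(score_individuals(mod, test))
      data.frame(model = label, maf_ceiling = ceiling, p_threshold = p,
                 n_snps = nrow(snps), auc = auc_delong(s$case, s$ctrl)$auc,
                 tpr = tpr_full_specificity(s$case, s$ctrl)$tpr)
    }, error = function(e)
      data.frame(model = label, maf_ceiling = ceiling, p_threshold = p,
                 n_snps = nrow(snps), auc = NA_real_, tpr = NA_real_))
  }
  for (i in seq_len(nrow(cells))) {
    ce <- cells$ceiling[i]; p <- cells$p[i]
    snps <- select_model_snps(assoc, ce, p, direction)
    rows[[length(rows) + 1L]] <-
      eval_cell(snps, sprintf("maf<%g", ce), ce, p)
  }
  if (include_haplotype) {
    for (p in p_grid) {
      reps <- select_representatives(blocks, assoc, 0.4, p, direction)
      snps <- select_model_snps(assoc, 0.4, p, direction, restrict_to = reps)
      rows[[length(rows) + 1L]] <- eval_cell(snps, "haplotype", 0.4, p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Stratified k-fold cross-validation of the risk model
#'
#' Randomly partitions the cohort into `k` folds, stratified by case
#' status so every fold holds both classes. Within each fold the whole
#' pipeline is re-derived on the training portion only — minor-allele
#' orientation from the training controls, per-SNP logistic weights from
#' the training samples — so no information leaks from the held-out
#' fold. Each sample is validated exactly once and the per-fold metrics
#' are averaged.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of folds.
#' @param maf_ceiling,p_threshold,direction Model criteria.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `crossval_result`: `folds` (data frame
#'   with per-fold `auc`, `tpr`, `n_model_snps`, `n_test`), `mean_auc`,
#'   `mean_tpr`, `seed` and `assignment` (fold id per sample).
#' @export
kfold_cross_validate <- function(gm, k = 10L, maf_ceiling = 0.4,
                                 p_threshold = 0.05,
                                 direction = "cases_enriched", seed = 1L) {
  y <- gm$samples$phenotype
  idx_case <- which(y %in% "case")
  idx_ctrl <- which(y %in% "control")
  if (length(idx_case) < k || length(idx_ctrl) < k)
    stop("need at least k cases and k controls for stratified ", k, "-fold CV")
  set.seed(seed)
  fold <- integer(nrow(gm$calls))
  fold[sample(idx_case)] <- rep_len(seq_len(k), length(idx_case))
  fold[sample(idx_ctrl)] <- rep_len(seq_len(k), length(idx_ctrl))
  res <- lapply(seq_len(k), function(f) {
    test_i <- which(fold == f)
    model <- ma_risk(gm[-test_i, ], maf_ceiling, p_threshold, direction,
                     cohort_id = sprintf("fold %d training split", f))
    s <- split_scores(score_individuals(model, gm[test_i, ]))
    data.frame(fold = f, n_test = length(test_i),
               n_model_snps = nrow(model$snps),
               auc = auc_delong(s$case, s$ctrl)$auc,
               tpr = tpr_full_specificity(s$case, s$ctrl)$tpr)
  })
  folds <- do.call(rbind, res)
  structure(list(folds = folds, mean_auc = mean(folds$auc),
                 mean_tpr = mean(folds$tpr), seed = seed,
                 assignment = fold), class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(nrow(x$folds), "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean AUC %.4f, mean TPR at 100%% specificity %.4f\n",
              x$mean_auc, x$mean_tpr))
  invisible(x)
}

#' Validate case detection against an independent control population
#'
#' Reduces the model to the control cohort's panel, scores the controls,
#' and reports the fraction of (externally supplied) case scores lying
#' strictly above every control score, with an exact binomial CI. The
#' case scores must have been computed with the same reduced model for
#' the comparison to be meaningful.
#'
#' @param model An [ma_risk()] model.
#' @param control_matrix A [genotype_matrix()] of control samples.
#' @param case_scores Numeric vector of case scores from the reduced
#'   model (see [reduce_model_to_panel()]).
#' @param extra_control_scores Optional additional control scores pooled
#'   into the threshold (e.g. the training controls).
#' @return List as [tpr_full_specificity()], plus `n_controls` and
#'   `model` (the reduced model).
#' @export
control_only_validation <- function(model, control_matrix, case_scores,
                                    extra_control_scores = numeric(0)) {
  red <- reduce_model_to_panel(model, control_matrix$variants$snp_id)
  ctrl <- c(score_individuals(red, control_matrix)$score,
            extra_control_scores)
  out <- tpr_full_specificity(case_scores, ctrl)
  out$n_controls <- length(ctrl)
  out$model <- red
  out
}
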