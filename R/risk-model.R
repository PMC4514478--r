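#' Fit a weighted minor-allele risk model
#'
#' The central fitting function of the package. From a training
#' case/control cohort it (i) orients every SNP by its control
#' minor-allele frequency, (ii) fits a per-SNP logistic regression of
#' case status on minor-allele copies, and (iii) selects the SNPs whose
#' control MAF is below `maf_ceiling` and whose association p-value is
#' below `p_threshold` (both strict), optionally requiring the minor
#' allele to be more frequent in cases. Each selected SNP's weight is its
#' logistic coefficient; individuals are scored by summing weight x
#' (minor-allele copies / 2), so a heterozygote contributes half a
#' coefficient and a minor-allele homozygote a full one.
#'
#' @param train A [genotype_matrix()] with case and control samples.
#' @param maf_ceiling Control-MAF ceiling; SNPs at or above it are
#'   excluded (default 0.4, leaving out 0.4-0.5 SNPs whose minor-allele
#'   status is least certain).
#' @param p_threshold Association p-value threshold (default 0.05).
#' @param direction `"cases_enriched"` (default) keeps only SNPs whose
#'   minor allele is more frequent in cases than controls; `"any"`
#'   disables the filter.
#' @param ma_set,association Optional precomputed [compute_control_maf()]
#'   and [snp_association()] results for `train` (avoids refitting in
#'   sweeps).
#' @param cohort_id Free-text identifier of the training cohort.
#'
#' @return An object of class `ma_risk`: a list with `snps` (selected
#'   SNP table: `snp_id`, `chrom`, `pos`, `minor_allele`, `weight`,
#'   `control_maf`, `p_value`), `criteria`, `ma_set`, `association`,
#'   `train_scores` (a `score_profile` for the training samples),
#'   `n_train_cases`, `n_train_controls` and `call`.
#' @seealso [predict.ma_risk()], [reduce_model_to_panel()],
#'   [external_validate()], [kfold_cross_validate()]
#' @export
ma_risk <- function(train, maf_ceiling = 0.4, p_threshold = 0.05,
                    direction = c("cases_enriched", "any"),
                    ma_set = NULL, association = NULL,
                    cohort_id = "training") {
  direction <- match.arg(direction)
  if (is.null(ma_set)) ma_set <- compute_control_maf(train)
  if (is.null(association)) association <- snp_association(train, ma_set)
  snps <- select_model_snps(association, maf_ceiling, p_threshold, direction)
  if (nrow(snps) == 0L)
    stop("no SNP meets the selection criteria (maf_ceiling=", maf_ceiling,
         ", p_threshold=", p_threshold, ", direction=", direction, ")")
  obj <- structure(list(
    snps = snps,
    criteria = list(maf_ceiling = maf_ceiling, p_threshold = p_threshold,
                    direction = direction),
    ma_set = ma_set, association = association,
    n_train_cases = sum(train$samples$phenotype %in% "case"),
    n_train_controls = sum(train$samples$phenotype %in% "control"),
    cohort_id = cohort_id, call = match.call()), class = "ma_risk")
  obj$train_scores <- score_individuals(obj, train)
  obj
}

## selection rule shared by ma_risk and the sweep/haplotype paths
select_model_snps <- function(association, maf_ceiling, p_threshold,
                              direction = "cases_enriched",
                              restrict_to = NULL) {
  a <- association
  keep <- a$informative & a$converged & !is.na(a$p_value) &
    !is.na(a$control_maf) & a$control_maf < maf_ceiling &
    a$p_value < p_threshold
  if (direction == "cases_enriched")
    keep <- keep & !is.na(a$case_maf) & a$case_maf > a$control_maf
  if (!is.null(restrict_to)) keep <- keep & a$snp_id %in% restrict_to
  out <- a[which(keep), c("snp_id", "chrom", "pos", "minor_allele",
                          "coefficient", "control_maf", "p_value")]
  names(out)[names(out) == "coefficient"] <- "weight"
  rownames(out) <- NULL
  out
}

#' Score individuals with a fitted risk model
#'
#' A model SNP contributes `weight` for a minor-allele homozygote,
#' `0.5 * weight` for a heterozygote and 0 otherwise. Missing genotypes
#' contribute 0 and decrement the per-sample used-SNP count. Alleles are
#' matched by identity or strand complement; model SNPs absent from the
#' panel (or with irreconcilable alleles) are skipped.
#'
#' @param model An [ma_risk()] model.
#' @param gm A [genotype_matrix()] to score.
#' @return A `score_profile` data frame: `sample_id`, `phenotype`,
#'   `score`, `n_used` (non-missing model SNPs), `score_per_snp`
#'   (normalized optional column) and `flagged` (no usable SNP).
#' @export
score_individuals <- function(model, gm) {
  j <- match(model$snps$snp_id, gm$variants$snp_id)
  present <- !is.na(j)
  if (!any(present)) stop("no model SNP present in the variant panel")
  sn <- model$snps[present, ]
  j <- j[present]
  v <- gm$variants[j, ]
  other <- ifelse(v$counted == v$allele1, v$allele2, v$allele1)
  minor <- sn$minor_allele
  orient <- ifelse(minor == v$counted, 1L,
            ifelse(minor == other, -1L,
            ifelse(complement_allele(minor) == v$counted, 1L,
            ifelse(complement_allele(minor) == other, -1L, NA_integer_))))
  ok <- !is.na(orient)
  if (!any(ok)) stop("no model SNP with reconcilable alleles in the panel")
  sn <- sn[ok, ]; j <- j[ok]; orient <- orient[ok]
  d <- gm$calls[, j, drop = FALSE]
  fl <- which(orient < 0L)
  if (length(fl)) d[, fl] <- 2L - d[, fl, drop = FALSE]
  used <- rowSums(!is.na(d))
  d[is.na(d)] <- 0L
  score <- as.numeric((d / 2) %*% sn$weight)
  structure(data.frame(sample_id = gm$samples$sample_id,
                       phenotype = gm$samples$phenotype,
                       score = score, n_used = used,
                       score_per_snp = ifelse(used > 0L, score / used, NA_real_),
                       flagged = used == 0L,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("score_profile", "data.frame"))
}

#' Restrict a risk model to a reduced variant panel
#'
#' Used for external validation on a cohort genotyped on a different
#' array: only the model SNPs present on the target panel are kept,
#' without reweighting or renormalization.
#'
#' @param model An [ma_risk()] model.
#' @param snp_ids Character vector of SNP ids available on the panel.
#' @return The reduced `ma_risk` model; the retained fraction is stored
#'   in `model$reduction` and reported by `print()`.
#' @export
reduce_model_to_panel <- function(model, snp_ids) {
  keep <- model$snps$snp_id %in% snp_ids
  if (!any(keep)) stop("empty intersection between model SNPs and panel")
  full <- nrow(model$snps)
  model$snps <- model$snps[keep, ]
  rownames(model$snps) <- NULL
  model$reduction <- list(n_full = full, n_kept = sum(keep),
                          fraction_kept = sum(keep) / full)
  model
}

#' Classify samples by a hard score threshold
#'
#' @param scores A `score_profile` from [score_individuals()].
#' @param threshold Finite score threshold; a sample is predicted-case
#'   iff its score is strictly greater.
#' @return Character vector (`"predicted-case"` / `"predicted-control"`)
#'   aligned with `scores$sample_id`.
#' @export
threshold_classify <- function(scores, threshold) {
  stopifnot(is.finite(threshold) || threshold == -Inf || threshold == Inf)
  ifelse(scores$score > threshold, "predicted-case", "predicted-control")
}

#' @export
print.ma_risk <- function(x, ...) {
  cat("Weighted minor-allele risk model (ma_risk)\n")
  cat(sprintf("  %d SNPs selected (control MAF < %g, p < %g, direction: %s)\n",
              nrow(x$snps), x$criteria$maf_ceiling, x$criteria$p_threshold,
              x$criteria$direction))
  cat(sprintf("  trained on %d cases / %d controls (%s)\n",
              x$n_train_cases, x$n_train_controls, x$cohort_id))
  if (!is.null(x$reduction))
    cat(sprintf("  reduced to panel: %d of %d SNPs kept (%.1f%%)\n",
                x$reduction$n_kept, x$reduction$n_full,
                100 * x$reduction$fraction_kept))
  invisible(x)
}

#' @export
coef.ma_risk <- function(object, ...) {
  stats::setNames(object$snps$weight, object$snps$snp_id)
}

#' Predict method for minor-allele risk models
#'
#' @param object An [ma_risk()] model.
#' @param newdata A [genotype_matrix()]; omitted, the training scores are
#'   returned.
#' @param type `"score"` (a `score_profile`) or `"class"` (hard labels
#'   from [threshold_classify()]).
#' @param threshold Threshold used when `type = "class"`.
#' @param ... Unused.
#' @return A `score_profile` data frame or a character vector of labels.
#' @export
predict.ma_risk <- function(object, newdata = NULL,
                            type = c("score", "class"), threshold = 0, ...) {
  type <- match.arg(type)
  sc <- if (is.null(newdata)) object$train_scores
        else score_individuals(object, newdata)
  if (type == "score") sc else threshold_classify(sc, threshold)
}

#' @export
summary.ma_risk <- function(object, ...) {
  sc <- object$train_scores
  cs <- sc$score[sc$phenotype %in% "case"]
  ct <- sc$score[sc$phenotype %in% "control"]
  a <- auc_delong(cs, ct)
  t <- tpr_full_specificity(cs, ct)
  out <- list(model = object,
              in_sample_auc = a$auc, in_sample_auc_ci = a$ci,
              in_sample_tpr = t$tpr, in_sample_tpr_ci = t$ci,
              case_mean = mean(cs), control_mean = mean(ct))
  class(out) <- "summary.ma_risk"
  out
}

#' @export
print.summary.ma_risk <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training score means: cases %.3f, controls %.3f\n",
              x$case_mean, x$control_mean))
  cat(sprintf("  in-sample AUC %.3f (95%% CI %.3f-%.3f)  [optimistic: same data used to select and weight SNPs]\n",
              x$in_sample_auc, x$in_sample_auc_ci[1L], x$in_sample_auc_ci[2L]))
  cat(sprintf("  in-sample TPR at 100%% specificity %.3f (95%% CI %.3f-%.3f)\n",
              x$in_sample_tpr, x$in_sample_tpr_ci[1L], x$in_sample_tpr_ci[2L]))
  invisible(x)
}

#' Plot training score distributions of a risk model
#'
#' Kernel density estimates of the training weighted risk scores for
#' cases and controls.
#'
#' @param x An [ma_risk()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ma_risk <- function(x, ...) {
  sc <- x$train_scores
  dc <- stats::density(sc$score[sc$phenotype %in% "case"])
  dt <- stats::density(sc$score[sc$phenotype %in% "control"])
  graphics::plot(dc, col = "firebrick", lwd = 2,
                 xlim = range(dc$x, dt$x), ylim = range(0, dc$y, dt$y),
                 xlab = "weighted risk score", main = "Training score distributions",
                 ...)
  graphics::lines(dt, col = "steelblue", lwd = 2)
  graphics::legend("topleft", c("cases", "controls"), lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Simulate cohorts from a fitted risk model
#'
#' Treats the fitted model as generative truth: selected SNPs keep their
#' control MAFs as population frequencies and their weights as true
#' log-odds effects, and new case/control cohorts are drawn under the
#' same additive dosage disease model the package assumes.
#'
#' @param object An [ma_risk()] model.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param n_cases,n_controls Sizes of each simulated cohort.
#' @param ... Unused.
#' @return A list of `nsim` [genotype_matrix()] cohorts.
#' @export
simulate.ma_risk <- function(object, nsim = 1, seed = NULL,
                             n_cases = object$n_train_cases,
                             n_controls = object$n_train_controls, ...) {
  if (!is.null(seed)) set.seed(seed)
  sn <- object$snps
  truth <- data.frame(snp_id = sn$snp_id, chrom = sn$chrom, pos = sn$pos,
                      major_allele = "A", minor_allele = "B",
                      true_maf = pmax(sn$control_maf, 1e-3),
                      is_risk = sn$weight != 0, effect = sn$weight,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nsim), function(i)
    sample_cohort_from_truth(truth, n_cases, n_controls,
                             baseline_log_odds = -sum(truth$effect * truth$true_maf),
                             missing_rate = 0, ld = NULL,
                             attempt_cap_mult = 1000))
}

#' Write a risk model as tab-separated text
#'
#' @param model An [ma_risk()] model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_risk_model <- function(model, path) {
  utils::write.table(model$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a score profile as tab-separated text
#'
#' @param scores A `score_profile` from [score_individuals()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_score_profile <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
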