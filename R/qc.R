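#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value
#' is the total probability of heterozygote counts no more probable than
#' the observed one under the conditional (2^h multinomial) distribution.
#' Robust at small counts where the chi-square approximation breaks down.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (orientation-symmetric).
#' @return P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)  # monomorphic: single possible table
  h <- seq(rare %% 2, rare, by = 2)
  lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  lp <- lp - max(lp)
  prob <- exp(lp) / sum(exp(lp))
  obs <- prob[match(n_Aa, h)]
  min(1, sum(prob[prob <= obs * (1 + 1e-10)]))
}

qc_row <- function(filter, tested, removed, threshold) {
  data.frame(filter = filter, tested = tested, removed = removed,
             threshold = as.character(threshold), stringsAsFactors = FALSE)
}

genotype_counts <- function(gm, rows) {
  g <- gm$calls[rows, , drop = FALSE]
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  cbind(n2 = n2, n1 = n1, n0 = n0)
}

#' Filter SNPs violating Hardy-Weinberg equilibrium
#'
#' Removes SNPs whose exact HWE p-value is at or below `alpha`,
#' by default tested in controls only (standard case/control practice:
#' true disease association can distort HWE in cases).
#'
#' @param gm A [genotype_matrix()].
#' @param alpha Significance level; SNPs with p <= alpha are removed.
#' @param population `"controls"` (default) or `"all"`.
#' @return List with `matrix` (filtered) and `report` (one QC row).
#' @export
filter_hwe <- function(gm, alpha = 0.01, population = c("controls", "all")) {
  population <- match.arg(population)
  rows <- if (population == "controls")
    which(gm$samples$phenotype %in% "control") else seq_len(nrow(gm$calls))
  cnt <- genotype_counts(gm, rows)
  p <- vapply(seq_len(nrow(cnt)), function(j) {
    if (sum(cnt[j, ]) == 0) return(1)
    hwe_exact_test(cnt[j, 1L], cnt[j, 2L], cnt[j, 3L])
  }, numeric(1L))
  keep <- p > alpha
  list(matrix = gm[, which(keep)],
       report = qc_row("hwe", ncol(gm$calls), sum(!keep),
                       sprintf("p<=%g in %s", alpha, population)))
}

#' Filter SNPs on missingness and control MAF
#'
#' Removes a SNP iff its missing-call fraction exceeds `max_missing`
#' (strict) or its control-sample MAF is below `min_maf` (strict).
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction.
#' @param min_maf Minimum control minor-allele frequency.
#' @return List with `matrix` and `report` (one QC row per rule).
#' @export
filter_missing_and_maf <- function(gm, max_missing = 0.05, min_maf = 1e-4) {
  stopifnot(max_missing > 0, max_missing < 1, min_maf > 0, min_maf < 1)
  miss <- colMeans(is.na(gm$calls))
  ctrl <- which(gm$samples$phenotype %in% "control")
  f <- colMeans(gm$calls[ctrl, , drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0  # no control calls: treat as MAF 0
  drop_miss <- miss > max_missing
  drop_maf <- !drop_miss & maf < min_maf
  keep <- !(drop_miss | drop_maf)
  rep <- rbind(
    qc_row("missingness", ncol(gm$calls), sum(drop_miss),
           sprintf(">%g", max_missing)),
    qc_row("maf_floor", ncol(gm$calls) - sum(drop_miss), sum(drop_maf),
           sprintf("<%g", min_maf)))
  list(matrix = gm[, which(keep)], report = rep)
}

#' Ancestry principal components from the genetic relationship matrix
#'
#' Standardizes each SNP by its allele frequency, (g - 2p) /
#' sqrt(2p(1 - p)), averages cross-products over jointly non-missing
#' SNPs to form the genetic relationship matrix (GRM), and returns its
#' top eigenvectors ordered by decreasing eigenvalue.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components matrix), `values`
#'   (eigenvalues, non-increasing) and `n_snps_used`.
#' @export
genetic_relationship_pca <- function(gm, n_components = 3L) {
  n <- nrow(gm$calls)
  if (n < 2L) stop("need at least 2 samples")
  g <- gm$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1 & !is.na(p))
  if (length(poly) < 2L) stop("need at least 2 polymorphic SNPs")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2L, 2 * p)
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(z)
  z[!obs] <- 0
  grm <- (z %*% t(z)) / (obs %*% t(obs))
  eig <- eigen(grm, symmetric = TRUE)
  k <- min(n_components, n)
  scores <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- gm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, values = eig$values, n_snps_used = length(poly))
}

#' Exclude principal-component outliers
#'
#' Flags samples lying more than `sd_multiplier` standard deviations from
#' the mean on any of the first three components (single pass).
#'
#' @param pcs Result of [genetic_relationship_pca()].
#' @param sd_multiplier Outlyingness threshold in SD units.
#' @return List with `keep` (sample ids retained), `removed` (ids
#'   excluded) and `report`.
#' @export
exclude_pc_outliers <- function(pcs, sd_multiplier = 6) {
  sc <- pcs$scores[, seq_len(min(3L, ncol(pcs$scores))), drop = FALSE]
  dev <- abs(scale(sc))
  out <- rowSums(dev > sd_multiplier, na.rm = TRUE) > 0
  list(keep = rownames(sc)[!out], removed = rownames(sc)[out],
       report = qc_row("pc_outliers", nrow(sc), sum(out),
                       sprintf("%g SD on PC1-3", sd_multiplier)))
}

#' Remove duplicated individuals
#'
#' Computes pairwise genotype concordance on up to `max_snps` SNPs and,
#' for every pair at or above the threshold, drops the later sample
#' (deterministic order rule).
#'
#' @param gm A [genotype_matrix()].
#' @param concordance_threshold Fraction of identical non-missing calls
#'   above which a pair counts as duplicated; in (0.5, 1].
#' @param max_snps Concordance is evaluated on at most this many SNPs.
#' @return List with `matrix` and `report`.
#' @export
remove_duplicates <- function(gm, concordance_threshold = 0.99,
                              max_snps = 10000L) {
  stopifnot(concordance_threshold > 0.5, concordance_threshold <= 1)
  n <- nrow(gm$calls)
  m <- ncol(gm$calls)
  j <- if (m > max_snps) seq(1L, m, length.out = max_snps) else seq_len(m)
  g <- gm$calls[, j, drop = FALSE]
  match_mat <- matrix(0, n, n)
  obs <- (!is.na(g)) * 1
  for (val in 0:2) {
    ind <- (!is.na(g) & g == val) * 1
    match_mat <- match_mat + tcrossprod(ind)
  }
  valid <- tcrossprod(obs)
  conc <- match_mat / pmax(valid, 1)
  conc[valid == 0] <- 0
  drop <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    if (drop[i]) next
    dup <- which(conc[i, ] >= concordance_threshold)
    drop[dup[dup > i]] <- TRUE
  }
  list(matrix = gm[which(!drop), ],
       report = qc_row("duplicates", n, sum(drop),
                       sprintf(">=%g concordance", concordance_threshold)))
}

#' Apply the full sample/variant quality-control sequence
#'
#' Fixed, recorded order: duplicate removal, PC-outlier exclusion,
#' missingness/MAF filter, HWE filter.
#'
#' @param gm A [genotype_matrix()].
#' @param hwe_alpha,max_missing,min_maf,pc_sd_multiplier,concordance_threshold
#'   Filter thresholds (see the individual filters).
#' @param hwe_population Population the HWE test runs in.
#' @param run_pca Set `FALSE` to skip the PCA outlier step (e.g. for very
#'   small toy cohorts).
#' @return List with `matrix` (the QC-passed cohort) and `report` (a
#'   `qc_report` data frame, rows in application order).
#' @export
apply_qc <- function(gm, hwe_alpha = 0.01, max_missing = 0.05, min_maf = 1e-4,
                     pc_sd_multiplier = 6, concordance_threshold = 0.99,
                     hwe_population = "controls", run_pca = TRUE) {
  st1 <- remove_duplicates(gm, concordance_threshold)
  gm <- st1$matrix
  rep <- st1$report
  if (run_pca) {
    pcs <- genetic_relationship_pca(gm, 3L)
    st2 <- exclude_pc_outliers(pcs, pc_sd_multiplier)
    gm <- gm[st2$keep, ]
    rep <- rbind(rep, st2$report)
  }
  st3 <- filter_missing_and_maf(gm, max_missing, min_maf)
  gm <- st3$matrix
  rep <- rbind(rep, st3$report)
  st4 <- filter_hwe(gm, hwe_alpha, hwe_population)
  gm <- st4$matrix
  rep <- rbind(rep, st4$report)
  rep$order <- seq_len(nrow(rep))
  class(rep) <- c("qc_report", class(rep))
  list(matrix = gm, report = rep)
}

#' Write a QC report as tab-separated text
#'
#' @param report A `qc_report` data frame from [apply_qc()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
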