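#' Determine minor alleles from control allele frequencies
#'
#' The minor allele of each SNP is the allele that is less frequent among
#' the control samples (missing calls excluded from denominators). SNPs
#' with control MAF exactly 0.5, or with the minor allele absent from
#' both cases and controls, are flagged non-informative; SNPs with no
#' control calls cannot be oriented and are likewise non-informative.
#'
#' @param gm A [genotype_matrix()] with at least one control sample.
#' @return A `ma_set` data frame: `snp_id`, `minor_allele`,
#'   `control_maf`, `case_maf` (frequency of the minor allele in cases),
#'   `informative`, `n_control_called`.
#' @export
compute_control_maf <- function(gm) {
  ctrl <- which(gm$samples$phenotype %in% "control")
  if (length(ctrl) == 0L) stop("no control samples")
  cases <- which(gm$samples$phenotype %in% "case")
  gc <- gm$calls[ctrl, , drop = FALSE]
  n_called <- colSums(!is.na(gc))
  f_ctrl <- colSums(gc, na.rm = TRUE) / (2 * n_called)  # freq of counted allele
  f_case <- if (length(cases)) {
    ga <- gm$calls[cases, , drop = FALSE]
    colSums(ga, na.rm = TRUE) / (2 * colSums(!is.na(ga)))
  } else rep(NA_real_, ncol(gm$calls))

  v <- gm$variants
  other <- ifelse(v$counted == v$allele1, v$allele2, v$allele1)
  minor_is_counted <- !is.na(f_ctrl) & f_ctrl < 0.5
  minor <- ifelse(minor_is_counted, v$counted, other)
  control_maf <- pmin(f_ctrl, 1 - f_ctrl)
  case_maf <- ifelse(minor_is_counted, f_case, 1 - f_case)

  informative <- !is.na(f_ctrl) & f_ctrl != 0.5
  zero_both <- !is.na(control_maf) & control_maf == 0 &
    (is.na(case_maf) | case_maf == 0)
  informative <- informative & !zero_both
  minor[is.na(f_ctrl)] <- NA_character_

  structure(data.frame(snp_id = v$snp_id, minor_allele = minor,
                       control_maf = control_maf, case_maf = case_maf,
                       informative = informative, n_control_called = n_called,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ma_set", "data.frame"))
}

## samples x SNPs matrix of minor-allele copies, oriented by ma_set
minor_dosage_matrix <- function(gm, ma_set) {
  idx <- match(gm$variants$snp_id, ma_set$snp_id)
  if (anyNA(idx)) stop("ma_set does not cover the variant panel")
  ms <- ma_set[idx, ]
  d <- gm$calls
  fl <- which(!is.na(ms$minor_allele) &
                ms$minor_allele != gm$variants$counted)
  if (length(fl)) d[, fl] <- 2L - d[, fl, drop = FALSE]
  d
}

#' Per-individual minor allele content (MAC)
#'
#' MAC is the minor-allele burden of an individual: the number of minor
#' allele copies carried at informative, non-missing SNPs divided by the
#' number of allele slots assayed there (2 x called SNPs), so MAC lies in
#' \[0, 1\]. Missing genotypes drop out of both numerator and
#' denominator; non-informative SNPs are excluded entirely.
#'
#' @param gm A [genotype_matrix()].
#' @param ma_set Result of [compute_control_maf()] on the same panel.
#' @return A `mac_profile` data frame: `sample_id`, `phenotype`,
#'   `minor_copies`, `n_called`, `mac` (`NA`, with `undefined = TRUE`,
#'   for samples with no called informative SNP).
#' @export
compute_mac <- function(gm, ma_set) {
  keep <- ma_set$informative[match(gm$variants$snp_id, ma_set$snp_id)]
  d <- minor_dosage_matrix(gm, ma_set)[, which(keep), drop = FALSE]
  copies <- rowSums(d, na.rm = TRUE)
  called <- rowSums(!is.na(d))
  mac <- ifelse(called > 0L, copies / (2 * called), NA_real_)
  structure(data.frame(sample_id = gm$samples$sample_id,
                       phenotype = gm$samples$phenotype,
                       minor_copies = copies, n_called = called, mac = mac,
                       undefined = called == 0L,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("mac_profile", "data.frame"))
}

#' One-way ANOVA comparison of group means
#'
#' @param values_by_group Named list of numeric vectors, one per group
#'   (e.g. MAC values for cases and controls).
#' @return List with `F` and `p_value`. Degenerate zero-variance input
#'   with equal means returns `F = 0`, `p = 1`.
#' @export
compare_group_means <- function(values_by_group) {
  stopifnot(length(values_by_group) >= 2L,
            all(lengths(values_by_group) >= 2L))
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group) %||% seq_along(values_by_group),
                       lengths(values_by_group))))
  within_var <- max(vapply(values_by_group, stats::var, numeric(1L)))
  means <- vapply(values_by_group, mean, numeric(1L))
  if (within_var < .Machine$double.eps) {  # degenerate: no within-group spread
    if (max(means) - min(means) < .Machine$double.eps^0.5)
      return(list(F = 0, p_value = 1))
    return(list(F = Inf, p_value = 0))
  }
  tab <- summary(stats::aov(value ~ group, data = df))[[1L]]
  list(F = tab[1L, "F value"], p_value = tab[1L, "Pr(>F)"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Vectorized Newton/IRLS logistic fits of y on each column of G (minor
## allele copies, NA = missing) with an intercept. Returns one row per column.
logistic_irls_matrix <- function(G, y, tol = 1e-8, maxit = 50L) {
  n <- nrow(G)
  m <- ncol(G)
  obs <- !is.na(G)
  Gz <- G
  Gz[!obs] <- 0L
  storage.mode(Gz) <- "double"
  obs_d <- obs * 1

  n_obs <- colSums(obs_d)
  gsum <- colSums(Gz)
  var_num <- colSums(Gz * Gz) - gsum^2 / pmax(n_obs, 1)  # >0 iff non-constant
  has_both <- colSums(obs_d * (y == 1L)) > 0 & colSums(obs_d * (y == 0L)) > 0
  active <- n_obs > 0 & var_num > 1e-9 & has_both

  b0 <- numeric(m)
  b1 <- numeric(m)
  done <- !active
  for (iter in seq_len(maxit)) {
    eta <- sweep(sweep(Gz, 2L, b1, "*"), 2L, b0, "+")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu) * obs_d
    r <- (y - mu) * obs_d
    U0 <- colSums(r)
    U1 <- colSums(r * Gz)
    I00 <- colSums(w)
    I01 <- colSums(w * Gz)
    I11 <- colSums(w * Gz * Gz)
    det <- I00 * I11 - I01 * I01
    bad <- det <= 1e-12 | !is.finite(det)
    det[bad] <- 1
    db1 <- (I00 * U1 - I01 * U0) / det
    db0 <- (U0 - I01 * db1) / pmax(I00, 1e-12)
    db1[done | bad] <- 0
    db0[done | bad] <- 0
    b0 <- b0 + db0
    b1 <- b1 + db1
    done <- done | bad | (pmax(abs(db0), abs(db1)) < tol)
    if (all(done)) break
  }
  # final information for standard errors
  eta <- sweep(sweep(Gz, 2L, b1, "*"), 2L, b0, "+")
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu) * obs_d
  I00 <- colSums(w)
  I01 <- colSums(w * Gz)
  I11 <- colSums(w * Gz * Gz)
  det <- I00 * I11 - I01 * I01
  se <- sqrt(ifelse(det > 0, I00 / det, NA_real_))
  converged <- active & done & abs(b1) < 15 & is.finite(se) & se < 100
  z <- b1 / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- NA_real_
  p[converged & p == 0] <- .Machine$double.xmin
  out <- data.frame(coefficient = b1, se = se, p_value = p,
                    converged = converged)
  out$coefficient[!active] <- NA_real_
  out$se[!active] <- NA_real_
  out$p_value[!active] <- NA_real_
  out
}

#' Logistic association fit for a single SNP
#'
#' Maximum-likelihood logistic regression of case status on minor-allele
#' copy count (0/1/2) with an intercept, by iteratively reweighted least
#' squares (tolerance 1e-8, at most 50 iterations), with Wald asymptotic
#' p-value. Non-converged or separated fits are flagged.
#'
#' @param genotypes Numeric vector of minor-allele copies (NA missing).
#' @param phenotype Vector of 0/1 (or `"control"`/`"case"`) outcomes.
#' @return List: `coefficient` (log-odds per minor-allele copy), `se`,
#'   `p_value`, `converged`.
#' @export
fit_snp_logistic <- function(genotypes, phenotype) {
  if (is.character(phenotype) || is.factor(phenotype))
    phenotype <- as.integer(as.character(phenotype) == "case")
  keep <- !is.na(phenotype)
  fit <- logistic_irls_matrix(matrix(as.numeric(genotypes[keep])),
                              as.integer(phenotype[keep]))
  list(coefficient = fit$coefficient, se = fit$se, p_value = fit$p_value,
       converged = fit$converged)
}

#' Per-SNP logistic association table
#'
#' Fits the single-SNP logistic model at every informative SNP and
#' assembles coefficients (the per-SNP weighted risk scores), standard
#' errors, Wald p-values and case/control minor-allele frequencies.
#'
#' @param gm A [genotype_matrix()] with case and control samples.
#' @param ma_set Optional [compute_control_maf()] result; computed from
#'   `gm` when missing.
#' @return An `association_table` data frame with one row per SNP:
#'   `snp_id`, `chrom`, `pos`, `minor_allele`, `control_maf`, `case_maf`,
#'   `coefficient`, `se`, `p_value`, `converged`, `informative`.
#' @export
snp_association <- function(gm, ma_set = NULL) {
  if (is.null(ma_set)) ma_set <- compute_control_maf(gm)
  y <- phenotype01(gm)
  rows <- which(!is.na(y))
  if (!any(y[rows] == 1L) || !any(y[rows] == 0L))
    stop("need at least one case and one control")
  d <- minor_dosage_matrix(gm, ma_set)[rows, , drop = FALSE]
  ms <- ma_set[match(gm$variants$snp_id, ma_set$snp_id), ]
  fit <- logistic_irls_matrix(d, y[rows])
  fit[!ms$informative, c("coefficient", "se", "p_value")] <- NA_real_
  fit$converged[!ms$informative] <- FALSE
  structure(data.frame(snp_id = gm$variants$snp_id,
                       chrom = gm$variants$chrom, pos = gm$variants$pos,
                       minor_allele = ms$minor_allele,
                       control_maf = ms$control_maf, case_maf = ms$case_maf,
                       coefficient = fit$coefficient, se = fit$se,
                       p_value = fit$p_value, converged = fit$converged,
                       informative = ms$informative,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("association_table", "data.frame"))
}

#' Average per-SNP risk score by MAF bin
#'
#' Partitions the included SNPs into equal-width control-MAF bins on
#' (0, `maf_ceiling`], computes each sample's total weighted risk score
#' restricted to a bin's SNPs (coefficient x copies / 2), and reports the
#' sample mean divided by the bin's SNP count — the average risk score
#' per SNP, comparable across bins of different size.
#'
#' @param association An [snp_association()] table.
#' @param gm The [genotype_matrix()] the scores are computed over.
#' @param bins Number of equal-width MAF bins.
#' @param maf_ceiling Upper end of the binned MAF range.
#' @return Data frame with `bin`, `maf_lo`, `maf_hi`, `n_snps`,
#'   `average_score`; empty bins are omitted.
#' @export
maf_binned_average_risk <- function(association, gm, bins = 5L,
                                    maf_ceiling = 0.4) {
  a <- association
  use <- a$informative & a$converged & !is.na(a$control_maf) &
    a$control_maf > 0 & a$control_maf < maf_ceiling
  edges <- seq(0, maf_ceiling, length.out = bins + 1L)
  bin <- cut(a$control_maf, edges, labels = FALSE)
  ms <- structure(a[, c("snp_id", "minor_allele", "control_maf", "case_maf",
                        "informative")], class = c("ma_set", "data.frame"))
  d <- minor_dosage_matrix(gm, ms)
  d[is.na(d)] <- 0L
  contrib <- sweep(d / 2, 2L, ifelse(is.na(a$coefficient), 0, a$coefficient),
                   "*")
  out <- lapply(seq_len(bins), function(k) {
    j <- which(use & bin == k)
    if (!length(j)) return(NULL)
    total <- rowSums(contrib[, j, drop = FALSE])
    data.frame(bin = k, maf_lo = edges[k], maf_hi = edges[k + 1L],
               n_snps = length(j), average_score = mean(total) / length(j))
  })
  do.call(rbind, out)
}
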