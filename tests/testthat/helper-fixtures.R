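# Hand-buildable genotype matrices and independent oracles used across tests.

toy_gm <- function(calls, phenotype, pos = NULL, chrom = "1",
                   allele1 = "A", allele2 = "G") {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  variants <- data.frame(
    chrom = rep_len(chrom, m),
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    snp_id = sprintf("t%03d", seq_len(m)),
    allele1 = rep_len(allele1, m), allele2 = rep_len(allele2, m),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(calls))),
    phenotype = phenotype, stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples)
}

quick_sim <- function(seed = 1, n_cases = 100, n_controls = 100, n_snps = 200,
                      n_risk = 0, effect = 0.3, missing_rate = 0.01, ...) {
  simulate_cohort(sim_config(
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
    n_risk_snps = n_risk,
    effect_size_spec = list(mean = effect, sd = 0.05, sign = "positive"),
    missing_rate = missing_rate, seed = seed, ...))
}

# Conditional HWE distribution derived independently via dmultinom
# conditioning: P(table | allele counts) is proportional to the
# multinomial HWE probability at any allele frequency.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  p <- 0.3
  pr <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    stats::dmultinom(c(aa, h, n - aa - h), prob = c(p^2, 2 * p * (1 - p),
                                                   (1 - p)^2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Brute-force pair-counting AUC with half credit for ties.
auc_pair_oracle <- function(case_scores, control_scores) {
  cmp <- outer(case_scores, control_scores,
               function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# Orientation-aware equality of two genotype matrices over the same panel.
expect_gm_equivalent <- function(a, b) {
  expect_identical(a$variants$snp_id, b$variants$snp_id)
  expect_identical(a$samples$sample_id, b$samples$sample_id)
  for (j in seq_len(ncol(a$calls))) {
    x <- a$calls[, j]
    y <- b$calls[, j]
    if (!identical(a$variants$counted[j], b$variants$counted[j])) y <- 2L - y
    expect_identical(unname(as.integer(x)), unname(as.integer(y)))
  }
}
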