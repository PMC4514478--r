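test_that("minor alleles are determined from control frequencies", {
  # 10 controls, 4 copies of the counted allele in 20 slots -> MAF 0.2
  calls <- matrix(c(rep(0L, 5), 2L, 1L, 1L, rep(0L, 7),
                    rep(1L, 15)), 15, 2)
  gm <- toy_gm(calls, c(rep("case", 5), rep("control", 10)))
  ms <- compute_control_maf(gm)
  expect_equal(ms$control_maf[1], 0.2)
  expect_identical(ms$minor_allele[1], "A")  # counted allele is the rarer one
  # control MAF exactly 0.5 -> non-informative
  expect_equal(ms$control_maf[2], 0.5)
  expect_false(ms$informative[2])
  # controls all hom for allele1: minor allele is allele2, informative
  # only if cases carry it
  calls3 <- cbind(c(1L, 1L, 2L, 2L), c(2L, 2L, 2L, 2L))
  gm3 <- toy_gm(calls3, c("case", "case", "control", "control"))
  ms3 <- compute_control_maf(gm3)
  expect_equal(ms3$control_maf, c(0, 0))
  expect_identical(ms3$minor_allele, c("G", "G"))
  expect_true(ms3$informative[1])    # case MAF > 0
  expect_false(ms3$informative[2])   # MAF 0 in both groups
})

test_that("MAC is the per-allele minor-allele proportion over informative SNPs", {
  # sample 1: het at one of two informative SNPs, hom-major at the other
  calls <- rbind(c(1L, 0L), c(2L, 2L), c(0L, NA), c(0L, 0L), c(1L, 1L))
  gm <- toy_gm(calls, c("case", "case", "case", "control", "control"))
  # orient: make counted allele the minor one (controls carry 2 of 8 copies)
  ms <- compute_control_maf(gm)
  expect_true(all(ms$informative))
  mac <- compute_mac(gm, ms)
  expect_equal(mac$mac[1], 1 / 4)           # 1 copy / 4 slots
  expect_equal(mac$mac[2], 1)               # hom-minor everywhere
  expect_equal(mac$n_called[3], 1L)         # missing drops the slot
  expect_equal(mac$mac[3], 0)
  expect_true(all(mac$mac >= 0 & mac$mac <= 1))
})

test_that("MAC is invariant to SNP order, padding and allele orientation", {
  sim <- quick_sim(seed = 21, n_cases = 40, n_controls = 40, n_snps = 100,
                   missing_rate = 0.05)
  gm <- sim$cohort
  ms <- compute_control_maf(gm)
  mac <- compute_mac(gm, ms)
  perm <- sample(ncol(gm$calls))
  mac_perm <- compute_mac(gm[, perm], compute_control_maf(gm[, perm]))
  expect_equal(mac$mac, mac_perm$mac)
  # flipping counted alleles must not change MAC
  gm_fl <- flip_counted(gm, seq(1, 100, by = 3))
  mac_fl <- compute_mac(gm_fl, compute_control_maf(gm_fl))
  expect_equal(mac$mac, mac_fl$mac)
  # appending a non-informative (control MAF 0.5) SNP changes nothing
  gm2 <- gm
  gm2$calls <- cbind(gm$calls, pad = rep(1L, 80))
  gm2$variants <- rbind(gm$variants,
                        data.frame(chrom = "1", pos = 999999L, snp_id = "pad",
                                   allele1 = "A", allele2 = "G", counted = "A"))
  mac_pad <- compute_mac(gm2, compute_control_maf(gm2))
  expect_equal(mac$mac, mac_pad$mac)
})

test_that("one-way ANOVA matches the squared pooled t statistic", {
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(sample(10:40, 1), mean = runif(1))
    b <- rnorm(sample(10:40, 1))
    res <- compare_group_means(list(g1 = a, g2 = b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
  expect_equal(compare_group_means(list(a = c(1, 1, 1), b = c(1, 1, 1))),
               list(F = 0, p_value = 1))
})

test_that("single-SNP logistic fit agrees with glm and the 2x2 closed form", {
  set.seed(11)
  n <- 300
  y <- rep(c(1L, 0L), n / 2)
  # binary genotype: coefficient equals the 2x2 table log odds ratio
  g <- rbinom(n, 1, 0.3)
  fit <- fit_snp_logistic(g, y)
  tab <- table(factor(g, 0:1), factor(y, 0:1))
  lor <- log((tab["1", "1"] / tab["0", "1"]) / (tab["1", "0"] / tab["0", "0"]))
  expect_lt(abs(fit$coefficient - lor), 1e-7)
  # dosage genotypes with missing values: glm oracle
  for (i in 1:25) {
    g <- rbinom(n, 2, runif(1, 0.05, 0.45))
    g[sample(n, 10)] <- NA
    fit <- fit_snp_logistic(g, y)
    ref <- suppressWarnings(glm(y ~ g, family = binomial,
                                control = glm.control(epsilon = 1e-12)))
    co <- summary(ref)$coefficients
    expect_lt(abs(fit$coefficient - co[2, 1]), 1e-6)
    expect_lt(abs(fit$p_value - co[2, 4]), 1e-6)
    expect_true(fit$converged)
  }
  # identically distributed groups: coefficient ~ 0
  g0 <- rep(c(0L, 1L, 2L), 100)
  fit0 <- fit_snp_logistic(g0, rep(c(1L, 0L), 150))
  expect_lt(abs(fit0$coefficient), 0.2)
  expect_gt(fit0$p_value, 0.3)
  # degenerate inputs are flagged, not trusted
  expect_false(fit_snp_logistic(rep(1L, n), y)$converged)
  expect_false(fit_snp_logistic(c(rep(0L, 150), rep(2L, 150)),
                                c(rep(1L, 150), rep(0L, 150)))$converged)
})

test_that("association table respects orientation and informativeness", {
  sim <- quick_sim(seed = 13, n_cases = 80, n_controls = 80, n_snps = 60,
                   missing_rate = 0.03)
  gm <- sim$cohort
  assoc <- snp_association(gm)
  expect_true(all(assoc$p_value > 0 & assoc$p_value <= 1, na.rm = TRUE))
  expect_true(all(is.finite(assoc$coefficient[assoc$converged])))
  # flipping the counted allele leaves the minor-allele coefficient alone
  gm_fl <- flip_counted(gm, 1:30)
  assoc_fl <- snp_association(gm_fl)
  expect_equal(assoc$coefficient, assoc_fl$coefficient, tolerance = 1e-10)
  expect_identical(assoc$minor_allele, assoc_fl$minor_allele)
})

test_that("MAF-binned average risk scores partition the SNP set", {
  sim <- quick_sim(seed = 17, n_cases = 100, n_controls = 100, n_snps = 300,
                   n_risk = 30, effect = 0.4)
  gm <- sim$cohort
  assoc <- snp_association(gm)
  bins <- maf_binned_average_risk(assoc, gm, bins = 5, maf_ceiling = 0.4)
  included <- sum(assoc$informative & assoc$converged &
                    assoc$control_maf > 0 & assoc$control_maf < 0.4,
                  na.rm = TRUE)
  expect_equal(sum(bins$n_snps), included)
  expect_true(all(bins$maf_hi <= 0.4 + 1e-12))
  # a single bin equals total mean score over all included SNPs
  one <- maf_binned_average_risk(assoc, gm, bins = 1, maf_ceiling = 0.4)
  expect_equal(one$n_snps, included)
  expect_equal(nrow(one), 1L)
})
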