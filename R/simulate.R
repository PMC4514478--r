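#' Simulation configuration for synthetic case/control cohorts
#'
#' Bundles the generative parameters of the synthetic cohort model:
#' population minor-allele frequencies drawn from a scaled Beta spectrum,
#' Hardy-Weinberg genotypes given frequency, an additive log-odds disease
#' model on minor-allele dosage (copies / 2, so a heterozygote carries
#' half an effect), independent per-genotype missingness, and variant
#' positions laid down on synthetic autosomes so that bp-window
#' operations are exercisable.
#'
#' @param n_cases,n_controls Requested cohort sizes.
#' @param n_snps Number of biallelic autosomal SNPs.
#' @param maf_spectrum List with `shape1`, `shape2` (Beta shape
#'   parameters) and `floor`, `ceiling` in (0, 0.5]; population MAFs are
#'   `floor + (ceiling - floor) * Beta(shape1, shape2)`.
#' @param n_risk_snps Number of SNPs with a non-zero disease effect.
#' @param effect_size_spec List with `mean`, `sd` and `sign`
#'   (`"positive"` takes absolute values, `"any"` leaves signs as drawn)
#'   for the per-risk-SNP log-odds per unit dosage.
#' @param baseline_log_odds Intercept of the disease model; 0 corresponds
#'   to a balanced virtual population, appropriate for case/control
#'   sampling designs where prevalence is not modelled.
#' @param missing_rate Per-genotype missing probability in \[0, 1).
#' @param n_chromosomes Number of synthetic autosomes positions are
#'   spread over.
#' @param bp_spacing Mean inter-SNP spacing in bp (spacings are uniform
#'   on (0, 2 * bp_spacing)).
#' @param ld List `NULL` (independent SNPs, the default) or
#'   `list(block_size =, flip_prob =)` activating a block-copula mode:
#'   within blocks of `block_size` adjacent SNPs each haplotype carries
#'   one latent uniform variate, so that neighbouring SNPs are correlated
#'   (r2 decays with `flip_prob`); Hardy-Weinberg still holds marginally.
#' @param attempt_cap_mult Rejection-sampling cap: simulation fails if
#'   quotas are still unmet after `attempt_cap_mult * (n_cases +
#'   n_controls)` virtual individuals.
#' @param seed Integer seed; all stochastic draws flow from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 500L, n_controls = 500L, n_snps = 5000L,
                       maf_spectrum = list(shape1 = 1, shape2 = 2.2,
                                           floor = 0.01, ceiling = 0.5),
                       n_risk_snps = 50L,
                       effect_size_spec = list(mean = 0.05, sd = 0.02,
                                               sign = "positive"),
                       baseline_log_odds = 0,
                       missing_rate = 0.01,
                       n_chromosomes = 22L,
                       bp_spacing = 20000,
                       ld = NULL,
                       attempt_cap_mult = 100,
                       seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_snps = as.integer(n_snps), maf_spectrum = maf_spectrum,
              n_risk_snps = as.integer(n_risk_snps),
              effect_size_spec = effect_size_spec,
              baseline_log_odds = baseline_log_odds,
              missing_rate = missing_rate,
              n_chromosomes = as.integer(n_chromosomes),
              bp_spacing = bp_spacing, ld = ld,
              attempt_cap_mult = attempt_cap_mult, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cases >= 0L, n_controls >= 0L, n_snps >= 1L,
              n_risk_snps >= 0L, n_risk_snps <= n_snps,
              maf_spectrum$floor > 0, maf_spectrum$ceiling <= 0.5,
              maf_spectrum$floor <= maf_spectrum$ceiling,
              missing_rate >= 0, missing_rate < 1,
              n_chromosomes >= 1L, bp_spacing > 0)
  })
  class(cfg) <- "sim_config"
  cfg
}

## Draw the generative truth (positions, frequencies, effects) for m SNPs.
draw_truth <- function(cfg, m = cfg$n_snps, id_offset = 0L) {
  sp <- cfg$maf_spectrum
  maf <- sp$floor + (sp$ceiling - sp$floor) *
    stats::rbeta(m, sp$shape1, sp$shape2)
  chrom <- sort(sample.int(cfg$n_chromosomes, m, replace = TRUE))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(pmax(1L, as.integer(
      stats::runif(length(idx), 0, 2 * cfg$bp_spacing))))
  }
  es <- cfg$effect_size_spec
  effect <- numeric(m)
  risk <- rep(FALSE, m)
  if (cfg$n_risk_snps > 0L) {
    risk[sample.int(m, min(cfg$n_risk_snps, m))] <- TRUE
    eff <- stats::rnorm(sum(risk), es$mean, es$sd)
    if (identical(es$sign, "positive")) eff <- abs(eff)
    effect[risk] <- eff
  }
  bases <- c("A", "C", "G", "T")
  al <- t(vapply(seq_len(m), function(i) sample(bases, 2L), character(2L)))
  data.frame(snp_id = sprintf("snp%06d", id_offset + seq_len(m)),
             chrom = chrom, pos = pos,
             major_allele = al[, 1L], minor_allele = al[, 2L],
             true_maf = maf, is_risk = risk, effect = effect,
             stringsAsFactors = FALSE)
}

## Genotypes (minor-allele copies) for n individuals under HWE, optionally
## with block-copula LD: each haplotype carries one latent allele per block
## (frequency = the block head's MAF) that every member SNP copies with an
## independent flip probability, giving high r2 within blocks while each
## SNP marginally stays a Hardy-Weinberg draw.
draw_genotypes <- function(n, truth, ld = NULL) {
  m <- nrow(truth)
  if (is.null(ld)) {
    g <- matrix(stats::rbinom(n * m, 2L, rep(truth$true_maf, each = n)), n, m)
  } else {
    block <- ceiling(seq_len(m) / ld$block_size)
    head_maf <- truth$true_maf[match(unique(block), block)]
    hap <- function() {
      latent <- matrix(stats::rbinom(n * max(block), 1L,
                                     rep(head_maf, each = n)), n)
      a <- latent[, block, drop = FALSE]
      flip <- matrix(stats::runif(n * m) < ld$flip_prob, n, m)
      a[flip] <- 1L - a[flip]
      a
    }
    g <- hap() + hap()
  }
  storage.mode(g) <- "integer"
  g
}

## marginal allele frequency implied by the block-copula mode
ld_marginal_maf <- function(truth, ld) {
  block <- ceiling(seq_len(nrow(truth)) / ld$block_size)
  head_maf <- truth$true_maf[match(unique(block), block)][block]
  head_maf * (1 - ld$flip_prob) + (1 - head_maf) * ld$flip_prob
}

## Core rejection sampler shared by simulate_cohort and simulate_cohort_pair.
sample_cohort_from_truth <- function(truth, n_cases, n_controls,
                                     baseline_log_odds, missing_rate,
                                     ld, attempt_cap_mult,
                                     id_prefix = "ind") {
  need <- n_cases + n_controls
  cap <- ceiling(attempt_cap_mult * max(need, 1L))
  got_case <- got_ctrl <- 0L
  drawn <- 0L
  case_rows <- vector("list", 0L)
  ctrl_rows <- vector("list", 0L)
  eff <- truth$effect
  while ((got_case < n_cases || got_ctrl < n_controls) && drawn < cap) {
    batch <- min(max(need, 200L), cap - drawn)
    g <- draw_genotypes(batch, truth, ld)
    drawn <- drawn + batch
    lia <- baseline_log_odds + as.numeric(g %*% eff) / 2
    is_case <- stats::runif(batch) < stats::plogis(lia)
    need_case <- n_cases - got_case
    need_ctrl <- n_controls - got_ctrl
    take_case <- which(is_case)[seq_len(min(sum(is_case), need_case))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), need_ctrl))]
    if (length(take_case)) {
      case_rows[[length(case_rows) + 1L]] <- g[take_case, , drop = FALSE]
      got_case <- got_case + length(take_case)
    }
    if (length(take_ctrl)) {
      ctrl_rows[[length(ctrl_rows) + 1L]] <- g[take_ctrl, , drop = FALSE]
      got_ctrl <- got_ctrl + length(take_ctrl)
    }
  }
  if (got_case < n_cases || got_ctrl < n_controls)
    stop("case/control quota unreachable after ", drawn,
         " virtual individuals (", got_case, "/", n_cases, " cases, ",
         got_ctrl, "/", n_controls, " controls); adjust baseline_log_odds")
  g <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_
  storage.mode(g) <- "integer"
  n <- nrow(g)
  samples <- data.frame(
    sample_id = sprintf("%s%05d", id_prefix, seq_len(n)),
    phenotype = rep(c("case", "control"), c(n_cases, n_controls)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  variants <- data.frame(chrom = as.character(truth$chrom), pos = truth$pos,
                         snp_id = truth$snp_id,
                         allele1 = truth$major_allele,
                         allele2 = truth$minor_allele,
                         counted = truth$minor_allele,
                         stringsAsFactors = FALSE)
  genotype_matrix(g, variants, samples)
}

#' Simulate a case/control cohort with known generative truth
#'
#' Draws population MAFs from the configured spectrum, genotypes in
#' Hardy-Weinberg proportions, assigns case status by a logistic model on
#' summed minor-allele dosage (copies / 2) times the true effects, and
#' fills the requested case/control quotas by rejection sampling from a
#' virtual population, so that controls stay in HWE. Missing genotypes
#' are masked independently. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a [genotype_matrix()] whose counted allele
#'   is the true population minor allele) and `truth` (per-SNP data frame
#'   with `true_maf`, `is_risk` and `effect`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- draw_truth(config)
  cohort <- sample_cohort_from_truth(
    truth, config$n_cases, config$n_controls, config$baseline_log_odds,
    config$missing_rate, config$ld, config$attempt_cap_mult)
  # record the flip-adjusted marginal frequency the copula mode realizes
  if (!is.null(config$ld)) truth$true_maf <- ld_marginal_maf(truth, config$ld)
  list(cohort = cohort, truth = truth)
}

#' Simulate a pair of cohorts sharing part of their variant panel
#'
#' Both cohorts are drawn from one generative truth; their variant panels
#' intersect in exactly `round(snp_overlap_fraction * min(n_snps))` SNPs,
#' emulating case/control datasets genotyped on overlapping but
#' non-identical arrays. Disease status in each cohort depends on the
#' full risk-SNP set whether or not a risk SNP is on that cohort's panel.
#'
#' @param config_a,config_b [sim_config()]s for the two cohorts (the MAF
#'   spectrum, effects and disease model are taken from `config_a`).
#' @param snp_overlap_fraction Fraction in \[0, 1\] of the smaller panel
#'   shared between the two cohorts.
#' @return List with `a`, `b` (each a list of `cohort` and `truth`
#'   restricted to that cohort's panel), `truth` (union panel) and
#'   `shared_snp_ids`.
#' @export
simulate_cohort_pair <- function(config_a, config_b = config_a,
                                 snp_overlap_fraction = 1) {
  stopifnot(inherits(config_a, "sim_config"),
            snp_overlap_fraction >= 0, snp_overlap_fraction <= 1)
  set.seed(config_a$seed)
  na <- config_a$n_snps; nb <- config_b$n_snps
  n_shared <- round(snp_overlap_fraction * min(na, nb))
  m_union <- na + nb - n_shared
  truth <- draw_truth(config_a, m = m_union)
  idx <- sample.int(m_union)  # random panel assignment
  shared <- idx[seq_len(n_shared)]
  only_a <- idx[seq_len(na - n_shared) + n_shared]
  only_b <- idx[seq_len(nb - n_shared) + na]
  ja <- sort(c(shared, only_a))
  jb <- sort(c(shared, only_b))

  full_a <- sample_cohort_from_truth(
    truth, config_a$n_cases, config_a$n_controls, config_a$baseline_log_odds,
    config_a$missing_rate, config_a$ld, config_a$attempt_cap_mult, "a")
  full_b <- sample_cohort_from_truth(
    truth, config_b$n_cases, config_b$n_controls, config_a$baseline_log_odds,
    config_b$missing_rate, config_a$ld, config_b$attempt_cap_mult, "b")

  list(a = list(cohort = full_a[, ja], truth = truth[ja, ]),
       b = list(cohort = full_b[, jb], truth = truth[jb, ]),
       truth = truth, shared_snp_ids = truth$snp_id[sort(shared)])
}

#' Write a simulation truth table as tab-separated text
#'
#' @param truth Truth data frame from [simulate_cohort()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
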