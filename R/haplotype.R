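#' Pairwise genotype r-squared between two SNPs
#'
#' Composite linkage-disequilibrium measure: the squared Pearson
#' correlation of minor (or counted) allele copy numbers across samples,
#' computed on pairwise-complete observations. Deterministic and
#' phase-free, a standard proxy for haplotype r2.
#'
#' @param gA,gB Numeric vectors of allele copies (NA = missing).
#' @return r2 in \[0, 1\], or `NA` if either SNP is monomorphic on the
#'   complete pairs or fewer than 2 complete pairs exist.
#' @export
pairwise_r2 <- function(gA, gB) {
  ok <- !is.na(gA) & !is.na(gB)
  if (sum(ok) < 2L) return(NA_real_)
  a <- gA[ok]; b <- gB[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Group map-ordered SNPs into LD blocks
#'
#' Greedy left-to-right agglomeration along each chromosome: the current
#' block is extended to the next SNP iff the SNP lies within `window_bp`
#' of the block's first position and its maximum genotype r2 with the
#' current members reaches `r2_min`; otherwise a new block starts. Every
#' SNP ends up in exactly one block (singletons allowed).
#'
#' @param gm A [genotype_matrix()] whose variants are position-sorted
#'   within chromosome (an error otherwise).
#' @param window_bp Maximum bp distance from block start (default 200 kb).
#' @param r2_min Minimum r2 to merge (default 0.5).
#' @return An object of class `hap_blocks`: list with `blocks` (data
#'   frame `block_id`, `chrom`, `start`, `end`, `n_members`) and
#'   `members` (list of SNP-id vectors, one per block).
#' @export
build_blocks <- function(gm, window_bp = 200000, r2_min = 0.5) {
  v <- gm$variants
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    if (is.unsorted(p)) stop("variants not position-sorted on chromosome ", ch)
  }
  g <- gm$calls
  block_of <- integer(nrow(v))
  bid <- 0L
  cur <- integer(0)   # member column indices of the open block
  cur_start <- NA_integer_
  cur_chrom <- ""
  for (j in seq_len(nrow(v))) {
    merge <- FALSE
    if (length(cur) && v$chrom[j] == cur_chrom &&
        v$pos[j] - cur_start <= window_bp) {
      r2 <- vapply(cur, function(k) pairwise_r2(g[, k], g[, j]), numeric(1L))
      merge <- any(!is.na(r2) & r2 >= r2_min)
    }
    if (!merge) {
      bid <- bid + 1L
      cur <- integer(0)
      cur_start <- v$pos[j]
      cur_chrom <- v$chrom[j]
    }
    cur <- c(cur, j)
    block_of[j] <- bid
  }
  members <- split(v$snp_id, block_of)
  idx <- split(seq_len(nrow(v)), block_of)
  blocks <- data.frame(
    block_id = as.integer(names(members)),
    chrom = vapply(idx, function(i) v$chrom[i[1L]], ""),
    start = vapply(idx, function(i) min(as.numeric(v$pos[i])), numeric(1L)),
    end = vapply(idx, function(i) max(as.numeric(v$pos[i])), numeric(1L)),
    n_members = lengths(members), stringsAsFactors = FALSE, row.names = NULL)
  structure(list(blocks = blocks, members = unname(members)),
            class = "hap_blocks")
}

#' @export
print.hap_blocks <- function(x, ...) {
  cat("hap_blocks:", nrow(x$blocks), "blocks,",
      sum(x$blocks$n_members), "SNPs,",
      sum(x$blocks$n_members == 1L), "singletons\n")
  invisible(x)
}

#' Select one representative SNP per LD block
#'
#' Within each block, the member with the best disease linkage (smallest
#' association p-value) among those meeting the selection criteria
#' (control MAF below the ceiling, p below the threshold) represents the
#' block; ties are broken towards the smaller bp position. Blocks with
#' no qualifying member contribute nothing.
#'
#' @param blocks A [build_blocks()] result.
#' @param association An [snp_association()] table covering the members.
#' @param maf_ceiling,p_threshold Minimal selection criteria.
#' @param direction As in [ma_risk()]; `"cases_enriched"` keeps only
#'   case-enriched minor alleles.
#' @return Character vector of representative SNP ids.
#' @export
select_representatives <- function(blocks, association, maf_ceiling = 0.4,
                                   p_threshold = 0.05,
                                   direction = "cases_enriched") {
  a <- association
  ok <- a$informative & a$converged & !is.na(a$p_value) &
    !is.na(a$control_maf) & a$control_maf < maf_ceiling &
    a$p_value < p_threshold
  if (direction == "cases_enriched")
    ok <- ok & !is.na(a$case_maf) & a$case_maf > a$control_maf
  ok_ids <- a$snp_id[ok]
  p <- stats::setNames(a$p_value, a$snp_id)
  pos <- stats::setNames(a$pos, a$snp_id)
  reps <- vapply(blocks$members, function(mem) {
    cand <- mem[mem %in% ok_ids]
    if (!length(cand)) return(NA_character_)
    best <- cand[p[cand] == min(p[cand])]
    best[order(pos[best])][1L]
  }, character(1L))
  reps[!is.na(reps)]
}

#' Write LD blocks as tab-separated text
#'
#' @param blocks A [build_blocks()] result.
#' @param path Output file path.
#' @param representatives Optional named selection from
#'   [select_representatives()]; matched back to blocks by membership.
#' @return Invisibly, `path`.
#' @export
write_blocks <- function(blocks, path, representatives = NULL) {
  df <- blocks$blocks
  if (!is.null(representatives)) {
    df$representative <- vapply(blocks$members, function(mem) {
      hit <- intersect(mem, representatives)
      if (length(hit)) hit[1L] else NA_character_
    }, character(1L))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
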