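#' Read PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PED/MAP into a [genotype_matrix()]. The
#' counted allele of each variant is initialized to the first allele seen
#' in the PED (`allele1`); genotype `0 0` becomes a missing call;
#' phenotype 1 maps to control, 2 to case, 0 or -9 to missing.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (length(nf) && any(nf < 4L))
    stop("MAP line ", which(nf < 4L)[1L], ": expected 4 fields, got ", nf[nf < 4L][1L])
  m <- length(map_fields)
  variants <- data.frame(
    chrom = vapply(map_fields, `[`, "", 1L),
    pos = as.integer(vapply(map_fields, `[`, "", 4L)),
    snp_id = vapply(map_fields, `[`, "", 2L),
    allele1 = NA_character_, allele2 = NA_character_,
    stringsAsFactors = FALSE)
  if (anyDuplicated(variants$snp_id))
    stop("duplicate SNP id in MAP: ",
         variants$snp_id[duplicated(variants$snp_id)][1L])

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  want <- 6L + 2L * m
  a1 <- rep(NA_character_, m)   # first allele observed -> counted
  a2 <- rep(NA_character_, m)
  calls <- matrix(NA_integer_, n, m)
  samples <- data.frame(sample_id = character(n), phenotype = NA_character_,
                        sex = "unknown", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1L]]
    if (length(f) != want)
      stop("PED line ", i, ": expected ", want, " fields, got ", length(f))
    samples$sample_id[i] <- f[2L]
    samples$sex[i] <- switch(f[5L], "1" = "male", "2" = "female", "unknown")
    samples$phenotype[i] <- switch(f[6L], "1" = "control", "2" = "case",
                                   NA_character_)
    g1 <- f[seq(7L, by = 2L, length.out = m)]
    g2 <- f[seq(8L, by = 2L, length.out = m)]
    miss <- g1 == "0" | g2 == "0"
    for (al in list(g1, g2)) {
      new <- !miss & is.na(a1)
      a1[new] <- al[new]
      new2 <- !miss & is.na(a2) & al != a1
      a2[new2] <- al[new2]
    }
    extra <- !miss & g1 != a1 & (is.na(a2) | g1 != a2)
    extra <- extra | (!miss & g2 != a1 & (is.na(a2) | g2 != a2))
    if (any(extra))
      stop("PED line ", i, ": more than two alleles at SNP ",
           variants$snp_id[which(extra)[1L]])
    calls[i, ] <- ifelse(miss, NA_integer_,
                         (g1 == a1) + (g2 == a1))
  }
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id in PED: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  variants$allele1 <- ifelse(is.na(a1), "0", a1)
  variants$allele2 <- ifelse(is.na(a2), "0", a2)  # "0" placeholder if monomorphic
  variants$counted <- variants$allele1
  genotype_matrix(calls, variants, samples)
}

#' Write PLINK text PED/MAP files
#'
#' @param gm A [genotype_matrix()].
#' @param out_prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped_map <- function(gm, out_prefix) {
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  v <- gm$variants
  writeLines(paste(v$chrom, v$snp_id, 0L, v$pos, sep = "\t"), map_path)

  other <- ifelse(v$counted == v$allele1, v$allele2, v$allele1)
  n <- nrow(gm$calls)
  lines <- character(n)
  sex_code <- c(male = "1", female = "2", unknown = "0")[gm$samples$sex]
  sex_code[is.na(sex_code)] <- "0"
  phen_code <- ifelse(is.na(gm$samples$phenotype), "-9",
                      ifelse(gm$samples$phenotype == "case", "2", "1"))
  for (i in seq_len(n)) {
    g <- gm$calls[i, ]
    g1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$counted, other))
    g2 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$counted, other))
    id <- gm$samples$sample_id[i]
    lines[i] <- paste(c(id, id, "0", "0", sex_code[i], phen_code[i],
                        rbind(g1, g2)), collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK transposed text TPED/TFAM files
#'
#' @param tped_path,tfam_path Paths to the TPED and TFAM files.
#' @return A [genotype_matrix()].
#' @export
read_tped_tfam <- function(tped_path, tfam_path) {
  fam <- strsplit(trimws(readLines(tfam_path)), "[ \t]+")
  fam <- fam[lengths(fam) > 0L]
  n <- length(fam)
  if (any(lengths(fam) != 6L)) stop("TFAM: expected 6 fields per line")
  samples <- data.frame(
    sample_id = vapply(fam, `[`, "", 2L),
    phenotype = vapply(fam, function(f)
      switch(f[6L], "1" = "control", "2" = "case", NA_character_), ""),
    sex = vapply(fam, function(f)
      switch(f[5L], "1" = "male", "2" = "female", "unknown"), ""),
    stringsAsFactors = FALSE)

  tl <- strsplit(trimws(readLines(tped_path)), "[ \t]+")
  tl <- tl[lengths(tl) > 0L]
  m <- length(tl)
  want <- 4L + 2L * n
  calls <- matrix(NA_integer_, n, m)
  variants <- data.frame(chrom = character(m), pos = NA_integer_,
                         snp_id = character(m), allele1 = "0", allele2 = "0",
                         stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- tl[[j]]
    if (length(f) != want)
      stop("TPED line ", j, ": expected ", want, " fields, got ", length(f))
    variants$chrom[j] <- f[1L]
    variants$snp_id[j] <- f[2L]
    variants$pos[j] <- as.integer(f[4L])
    g1 <- f[seq(5L, by = 2L, length.out = n)]
    g2 <- f[seq(6L, by = 2L, length.out = n)]
    miss <- g1 == "0" | g2 == "0"
    als <- unique(c(g1[!miss], g2[!miss]))
    if (length(als) > 2L)
      stop("TPED line ", j, ": more than two alleles at SNP ", f[2L])
    a1 <- if (length(als) >= 1L) als[1L] else "0"
    variants$allele1[j] <- a1
    variants$allele2[j] <- if (length(als) == 2L) als[2L] else "0"
    calls[, j] <- ifelse(miss, NA_integer_, (g1 == a1) + (g2 == a1))
  }
  if (anyDuplicated(variants$snp_id))
    stop("duplicate SNP id in TPED: ",
         variants$snp_id[duplicated(variants$snp_id)][1L])
  variants$counted <- variants$allele1
  genotype_matrix(calls, variants, samples)
}

#' Write PLINK transposed text TPED/TFAM files
#'
#' @param gm A [genotype_matrix()].
#' @param out_prefix Output path prefix; writes `<prefix>.tped` and
#'   `<prefix>.tfam`.
#' @return Invisibly, the two file paths.
#' @export
write_tped_tfam <- function(gm, out_prefix) {
  tfam_path <- paste0(out_prefix, ".tfam")
  tped_path <- paste0(out_prefix, ".tped")
  sex_code <- c(male = "1", female = "2", unknown = "0")[gm$samples$sex]
  sex_code[is.na(sex_code)] <- "0"
  phen_code <- ifelse(is.na(gm$samples$phenotype), "-9",
                      ifelse(gm$samples$phenotype == "case", "2", "1"))
  id <- gm$samples$sample_id
  writeLines(paste(id, id, 0L, 0L, sex_code, phen_code, sep = "\t"), tfam_path)

  v <- gm$variants
  other <- ifelse(v$counted == v$allele1, v$allele2, v$allele1)
  lines <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    g <- gm$calls[, j]
    g1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$counted[j], other[j]))
    g2 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$counted[j], other[j]))
    lines[j] <- paste(c(v$chrom[j], v$snp_id[j], "0", v$pos[j],
                        rbind(g1, g2)), collapse = "\t")
  }
  writeLines(lines, tped_path)
  invisible(c(tped = tped_path, tfam = tfam_path))
}

#' Intersect two variant panels and harmonize alleles
#'
#' Restricts both cohorts to the SNP ids they share, reconciles strand
#' flips by complement matching, harmonizes the counted allele so that
#' calls are directly comparable, and drops strand-ambiguous (A/T, C/G)
#' or allele-incompatible SNPs. Output variant order is identical in the
#' two matrices.
#'
#' @param a,b Two [genotype_matrix()] objects.
#' @param drop_ambiguous Drop A/T and C/G SNPs, whose strand cannot be
#'   resolved by complement matching (default `TRUE`; set `FALSE` only
#'   when both cohorts are known to be recorded on the same strand).
#' @return List with elements `a`, `b` (the restricted matrices),
#'   `n_shared`, `n_ambiguous_dropped` and `n_incompatible_dropped`.
#' @export
intersect_panels <- function(a, b, drop_ambiguous = TRUE) {
  shared <- intersect(a$variants$snp_id, b$variants$snp_id)
  if (length(shared) == 0L) stop("panels share no SNP ids")
  ja <- match(shared, a$variants$snp_id)
  jb <- match(shared, b$variants$snp_id)
  va <- a$variants[ja, ]
  vb <- b$variants[jb, ]

  pair <- function(x, y) paste(pmin(x, y), pmax(x, y))
  set_a <- pair(va$allele1, va$allele2)
  ambiguous <- drop_ambiguous & set_a %in% c("A T", "C G")
  set_b <- pair(vb$allele1, vb$allele2)
  set_b_c <- pair(complement_allele(vb$allele1), complement_allele(vb$allele2))
  direct <- set_b == set_a
  flipped <- !direct & set_b_c == set_a
  compatible <- direct | flipped
  keep <- compatible & !ambiguous

  n_amb <- sum(ambiguous & compatible)
  n_inc <- sum(!compatible)
  if (!any(keep)) stop("no compatible unambiguous SNPs left after reconciliation")

  a2 <- a[, ja[keep]]
  b2 <- b[, jb[keep]]
  # relabel b's alleles onto a's strand
  fl <- flipped[keep]
  b2$variants$allele1[fl] <- complement_allele(b2$variants$allele1[fl])
  b2$variants$allele2[fl] <- complement_allele(b2$variants$allele2[fl])
  b2$variants$counted[fl] <- complement_allele(b2$variants$counted[fl])
  # harmonize the counted allele to a's
  mismatch <- which(b2$variants$counted != a2$variants$counted)
  if (length(mismatch)) b2 <- flip_counted(b2, mismatch)
  b2$variants$allele1 <- a2$variants$allele1
  b2$variants$allele2 <- a2$variants$allele2

  list(a = a2, b = b2, n_shared = length(shared),
       n_ambiguous_dropped = n_amb, n_incompatible_dropped = n_inc)
}
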