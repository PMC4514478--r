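#' Construct a genotype matrix
#'
#' The in-memory container shared by every stage of the pipeline: a
#' samples x variants matrix of counted-allele copy numbers together with
#' variant metadata and sample phenotypes.
#'
#' @param calls Integer matrix, samples in rows and variants in columns.
#'   Entries are 0, 1, 2 (copies of the variant's counted allele) or `NA`
#'   for a missing call.
#' @param variants Data frame with columns `chrom`, `pos` (1-based bp),
#'   `snp_id`, `allele1`, `allele2`, and optionally `counted` (the allele
#'   whose copies `calls` counts; defaults to `allele1`).
#' @param samples Data frame with columns `sample_id`, `phenotype`
#'   (`"case"`, `"control"` or `NA`), and optionally `sex` (`"male"`,
#'   `"female"` or `"unknown"`).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(variants$counted)) variants$counted <- variants$allele1
  if (is.null(samples$sex)) samples$sex <- "unknown"
  rownames(variants) <- NULL
  rownames(samples) <- NULL

  if (nrow(samples) != nrow(calls))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  if (nrow(variants) != ncol(calls))
    stop("calls has ", ncol(calls), " columns but variants has ", nrow(variants))
  bad <- !is.na(calls) & (calls < 0L | calls > 2L)
  if (any(bad)) stop("calls must be in {0,1,2,NA}")
  if (anyDuplicated(variants$snp_id))
    stop("duplicate SNP ids: ", paste(utils::head(
      variants$snp_id[duplicated(variants$snp_id)], 3L), collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  ok_phen <- is.na(samples$phenotype) | samples$phenotype %in% c("case", "control")
  if (!all(ok_phen)) stop("phenotype must be 'case', 'control' or NA")
  dimnames(calls) <- list(samples$sample_id, variants$snp_id)

  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_case <- sum(x$samples$phenotype == "case", na.rm = TRUE)
  n_ctrl <- sum(x$samples$phenotype == "control", na.rm = TRUE)
  cat("genotype_matrix: ", nrow(x$calls), " samples (", n_case, " cases, ",
      n_ctrl, " controls) x ", ncol(x$calls), " variants\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%; chromosomes: %s\n", 100 * miss,
              paste(sort(unique(x$variants$chrom)), collapse = " ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i Sample index (logical, integer or sample ids).
#' @param j Variant index (logical, integer or SNP ids).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$variants$snp_id)
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE])
}

#' Re-orient the counted allele of selected variants
#'
#' Swaps the counted allele to the variant's other allele and maps every
#' non-missing call g to 2 - g. Doing it twice is the identity.
#'
#' @param x A [genotype_matrix()].
#' @param j Variant index (integer positions or SNP ids).
#' @return The re-oriented `genotype_matrix`.
#' @export
flip_counted <- function(x, j) {
  if (is.character(j)) j <- match(j, x$variants$snp_id)
  stopifnot(!anyNA(j))
  x$calls[, j] <- 2L - x$calls[, j, drop = FALSE]
  v <- x$variants
  other <- ifelse(v$counted[j] == v$allele1[j], v$allele2[j], v$allele1[j])
  x$variants$counted[j] <- other
  x
}

## phenotype as 0/1 (control/case), NA where missing
phenotype01 <- function(gm) {
  ifelse(gm$samples$phenotype == "case", 1L,
         ifelse(gm$samples$phenotype == "control", 0L, NA_integer_))
}

## reverse-complement lookup for strand reconciliation
ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", `0` = "0")

complement_allele <- function(a) {
  out <- unname(ALLELE_COMPLEMENT[a])
  out[is.na(out)] <- a[is.na(out)]
  out
}

#' Read a tab-separated phenotype table
#'
#' Two columns, `sample_id` and `phenotype` (`case`/`control`/`missing`),
#' with a header; used to override or supply phenotypes recorded outside
#' the PED file.
#'
#' @param path File path.
#' @return Data frame with `sample_id` and `phenotype` columns.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "phenotype") %in% names(df)))
    stop("phenotype table needs 'sample_id' and 'phenotype' columns")
  df$phenotype[!(df$phenotype %in% c("case", "control"))] <- NA_character_
  df[, c("sample_id", "phenotype")]
}

#' Apply a phenotype table to a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param phen Data frame as returned by [read_phenotype_table()].
#' @return `gm` with phenotypes replaced for the listed samples.
#' @export
apply_phenotype <- function(gm, phen) {
  idx <- match(gm$samples$sample_id, phen$sample_id)
  hit <- !is.na(idx)
  gm$samples$phenotype[hit] <- phen$phenotype[idx[hit]]
  gm
}
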