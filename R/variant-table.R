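# Shared in-memory data model: every module exchanges genotypes as an
# n_samples x m_snps integer matrix of alt-allele counts (0/1/2, NA = missing)
# plus a per-SNP table (chrom, pos, ref, alt, qual). The single source of truth
# for the code convention lives here.

#' Construct a variant table
#'
#' Bundles a per-SNP description with a samples-by-SNPs genotype matrix of
#' diploid alt-allele dosages. This is the container every pipeline stage
#' consumes and returns.
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   and optionally `qual`. Rows must be sorted by chromosome then position,
#'   with strictly increasing positions within a chromosome.
#' @param geno integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\} counting copies of the alternate allele.
#' @param samples character vector of sample identifiers (row names of `geno`).
#' @return An object of class `variant_table` with elements `snps`, `geno`,
#'   `samples`.
#' @export
variant_table <- function(snps, geno, samples = rownames(geno)) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snps)))
  if (is.null(snps$qual)) snps$qual <- NA_real_
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  if (nrow(snps) != ncol(geno))
    stop("geno must have one column per SNP row")
  if (length(samples) != nrow(geno))
    stop("sample IDs do not match genotype rows")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA (diploid only)")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(geno) <- samples
  structure(list(snps = snps, geno = geno, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$snps), "SNPs x", length(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = " "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of SNPs in a variant table
#' @param vt a `variant_table`.
#' @return integer count of SNP records.
#' @export
n_snps <- function(vt) nrow(vt$snps)

#' Subset a variant table by SNP index
#' @param vt a `variant_table`.
#' @param idx integer or logical index over SNPs (columns).
#' @return the subsetted `variant_table`, order preserved.
#' @export
subset_snps <- function(vt, idx) {
  variant_table(vt$snps[idx, , drop = FALSE],
                vt$geno[, idx, drop = FALSE], vt$samples)
}

#' Extract the genotype dosage matrix
#' @param vt a `variant_table`.
#' @return integer matrix (samples x SNPs) of codes 0/1/2/NA, with SNP
#'   identifiers `chrom_pos` as column names.
#' @export
genotypes <- function(vt) {
  g <- vt$geno
  colnames(g) <- snp_ids(vt)
  g
}

#' SNP identifiers of a variant table
#' @param vt a `variant_table`.
#' @return character vector `chrom_pos`.
#' @export
snp_ids <- function(vt) paste(vt$snps$chrom, vt$snps$pos, sep = "_")

#' Per-SNP minor allele frequency
#'
#' Computed from non-missing diploid dosages; always folded to `[0, 0.5]`.
#'
#' @param g genotype matrix (samples x SNPs) or a `variant_table`.
#' @return numeric vector of MAFs; NA where a column has no calls.
#' @export
snp_maf <- function(g) {
  if (inherits(g, "variant_table")) g <- g$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-SNP missing-call rate
#' @param g genotype matrix or `variant_table`.
#' @return numeric vector of per-SNP missing fractions.
#' @export
snp_missing_rate <- function(g) {
  if (inherits(g, "variant_table")) g <- g$geno
  colMeans(is.na(g))
}

# Mean-impute missing dosages column-wise (returns a double matrix).
impute_mean <- function(g) {
  if (inherits(g, "variant_table")) g <- g$geno
  g <- matrix(as.double(g), nrow(g), ncol(g), dimnames = dimnames(g))
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}
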