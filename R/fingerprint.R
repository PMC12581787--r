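# Minimal fingerprinting SNP sets: which sample pairs each SNP distinguishes,
# greedy set cover for the core set, and an exhaustive solver usable as an
# oracle on small candidate lists.

#' Filter SNPs suitable for allele-specific (KASP-style) assays
#'
#' Candidates must be called in every sample (zero missingness), have MAF at
#' least `min_maf`, lie in an exonic region, and pass flank QC (a proxy for
#' primer designability).
#'
#' @param vt a [variant_table()] genotyped on the target samples.
#' @param features a `feature_table`.
#' @param genome a `genome_sequence`.
#' @param min_maf MAF threshold (default 0.15).
#' @param flank,gc_min,gc_max flank-QC parameters (see [flank_qc()]).
#' @return integer vector of candidate SNP indices into `vt`.
#' @export
kasp_candidate_filter <- function(vt, features, genome, min_maf = 0.15,
                                  flank = 100, gc_min = 0.4, gc_max = 0.6) {
  miss <- snp_missing_rate(vt)
  maf <- snp_maf(vt)
  keep <- miss == 0 & !is.na(maf) & maf >= min_maf
  exonic <- vapply(seq_len(n_snps(vt)), function(i) {
    ch <- vt$snps$chrom[i]; p <- vt$snps$pos[i]
    for (g in features$genes) {
      if (g$chrom == ch && any(g$exons$start <= p & p <= g$exons$end))
        return(TRUE)
    }
    FALSE
  }, TRUE)
  keep <- keep & exonic
  fl <- vapply(which(keep), function(i)
    flank_qc(vt$snps$chrom[i], vt$snps$pos[i], genome, flank, gc_min,
             gc_max)$pass, TRUE)
  which(keep)[fl]
}

#' Which sample pairs each SNP distinguishes
#'
#' A pair is distinguished by a SNP when both calls are non-missing and the
#' genotype codes differ (heterozygote vs either homozygote counts as a
#' distinction). Pairs are unordered, enumerated as the columns of
#' `combn(n, 2)`.
#'
#' @param G genotype matrix (samples x SNPs) or a [variant_table()].
#' @return object of class `discrimination_index`: list with `pairs` (2 x P
#'   matrix of sample indices), `covers` (logical m x P matrix), `n_samples`.
#' @export
discrimination_matrix <- function(G) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  n <- nrow(G)
  if (n < 2) stop("need at least two samples")
  pairs <- combn(n, 2)
  gi <- G[pairs[1, ], , drop = FALSE]
  gj <- G[pairs[2, ], , drop = FALSE]
  covers <- t(!is.na(gi) & !is.na(gj) & gi != gj)  # m x P
  structure(list(pairs = pairs, covers = covers, n_samples = n,
                 snp_names = colnames(G)),
            class = "discrimination_index")
}

#' @export
print.discrimination_index <- function(x, ...) {
  cat("discrimination_index:", nrow(x$covers), "SNPs,",
      ncol(x$covers), "sample pairs;",
      sum(colSums(x$covers) > 0), "pairs distinguishable\n")
  invisible(x)
}

#' Greedy minimal core SNP set
#'
#' Iteratively selects the SNP distinguishing the most not-yet-distinguished
#' pairs (tie: the lower SNP index, i.e. locus order), stopping at full
#' coverage, at `max_snps`, or when no SNP covers a residual pair. Partial
#' coverage is reported, not an error.
#'
#' @param index a [discrimination_matrix()] result.
#' @param max_snps optional cap on the core-set size (NULL = no cap).
#' @return object of class `core_set`: `selected` (SNP indices in selection
#'   order), `coverage` (fraction of pairs distinguished), `residual_pairs`
#'   (2 x r matrix of still-identical sample pairs).
#' @export
greedy_core_set <- function(index, max_snps = NULL) {
  covers <- index$covers
  P <- ncol(covers)
  residual <- rep(TRUE, P)
  selected <- integer(0)
  while (any(residual) && (is.null(max_snps) || length(selected) < max_snps)) {
    gain <- covers %*% residual
    best <- which.max(gain)  # ties -> lowest index
    if (gain[best] == 0) break
    selected <- c(selected, best)
    residual <- residual & !covers[best, ]
  }
  structure(list(selected = selected,
                 coverage = 1 - sum(residual) / P,
                 residual_pairs = index$pairs[, residual, drop = FALSE],
                 n_samples = index$n_samples),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("core_set:", length(x$selected), "SNPs, coverage",
      sprintf("%.3f", x$coverage), "of sample pairs\n")
  if (ncol(x$residual_pairs))
    cat("  undistinguished pairs:", ncol(x$residual_pairs), "\n")
  invisible(x)
}

#' Exact minimum core set by exhaustive search
#'
#' Enumerates SNP subsets of increasing size; intended as an oracle for small
#' candidate lists (refuses more than `max_candidates`).
#'
#' @param index a [discrimination_matrix()] result.
#' @param max_candidates safety cap (default 20).
#' @return a `core_set` whose `selected` is a provably minimum-size cover, or
#'   the best-coverage set of minimum size if full coverage is unattainable.
#' @export
exact_core_set <- function(index, max_candidates = 20) {
  covers <- index$covers
  m <- nrow(covers)
  if (m > max_candidates) stop("too many candidates for exhaustive search")
  P <- ncol(covers)
  coverable <- colSums(covers) > 0
  target <- which(coverable)
  for (size in seq_len(m)) {
    sets <- combn(m, size)
    for (j in seq_len(ncol(sets))) {
      s <- sets[, j]
      cov <- colSums(covers[s, , drop = FALSE]) > 0
      if (all(cov[target])) {
        residual <- !cov
        return(structure(list(selected = s, coverage = 1 - sum(residual) / P,
                              residual_pairs = index$pairs[, residual,
                                                           drop = FALSE],
                              n_samples = index$n_samples),
                         class = "core_set"))
      }
    }
  }
  greedy_core_set(index)  # unreachable for coverable targets
}

#' Fingerprint table for a selected core set
#'
#' @param vt a [variant_table()].
#' @param core a `core_set` (indices into `vt`).
#' @return data.frame, samples in columns, SNPs in rows, VCF-style genotype
#'   strings (0/0, 0/1, 1/1, ./.).
#' @export
fingerprint_table <- function(vt, core) {
  g <- vt$geno[, core$selected, drop = FALSE]
  txt <- c("0/0", "0/1", "1/1")[g + 1L]
  txt[is.na(txt)] <- "./."
  out <- as.data.frame(t(matrix(txt, nrow(g), ncol(g))),
                       stringsAsFactors = FALSE)
  names(out) <- vt$samples
  rownames(out) <- snp_ids(vt)[core$selected]
  out
}
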