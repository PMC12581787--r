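# EMMAX-style association scan: simple-matching kinship, one-time spectral
# REML of the null mixed model, per-SNP generalized least squares with fixed
# variance components, effective-test significance threshold, genotype-group
# trait tests and pairwise LD.

#' Simple-matching-coefficient kinship
#'
#' `K(i,j)` is the mean, over co-observed sites, of the genotype matching
#' score: 1 for identical codes, 0.5 for codes differing by one alt allele,
#' 0 for opposite homozygotes. Diagonal is 1.
#'
#' @param G genotype matrix (samples x SNPs) or a [variant_table()].
#' @return symmetric n x n similarity matrix in `[0, 1]`.
#' @export
smc_kinship <- function(G) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  if (nrow(G) < 2) stop("need at least two samples")
  st <- pairwise_geno_stats(G)
  if (any(st$n_co == 0)) stop("sample pair with zero co-observed sites")
  K <- 1 - st$sum_absdiff / (2 * st$n_co)
  diag(K) <- 1
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

# spectral REML for y = Xb + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I).
# One-dimensional optimization over log lambda (lambda = sg2/se2) on the
# eigenvalues of the projected kernel (EMMA-style).
reml_kernel <- function(y, X, K, tol = 1e-8) {
  n <- length(y)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (q < ncol(X)) stop("X is rank deficient")
  K <- (K + t(K)) / 2
  ridge <- 1e-8 * mean(diag(K))
  eK <- eigen(K + diag(ridge, n), symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values)))
    stop("kinship matrix is not positive semidefinite")
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% (K + diag(ridge, n)) %*% S, symmetric = TRUE)
  xi <- pmax(es$values[seq_len(n - q)], 0)
  eta <- drop(crossprod(es$vectors[, seq_len(n - q), drop = FALSE], y))
  ll <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * xi + 1
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 -
                        log(sum(eta^2 / w))) - sum(log(w)))
  }
  grid <- seq(-12, 12, length.out = 49)
  vals <- vapply(grid, ll, 0)
  best <- which.max(vals)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)
  # keep the boundary if the grid end wins
  loglam <- if (opt$objective >= vals[best]) opt$maximum else grid[best]
  lam <- exp(loglam)
  w <- lam * xi + 1
  se2 <- sum(eta^2 / w) / (n - q)
  sg2 <- lam * se2
  # GLS fixed effects and BLUP via the full eigendecomposition
  d <- pmax(eK$values, 0)
  U <- eK$vectors
  vinv_diag <- 1 / (sg2 * d + se2)
  Uy <- crossprod(U, y); UX <- crossprod(U, X)
  XtVX <- crossprod(UX, vinv_diag * UX)
  XtVy <- crossprod(UX, vinv_diag * Uy)
  beta <- drop(solve(XtVX, XtVy))
  r <- y - drop(X %*% beta)
  u <- drop(U %*% ((sg2 * d * vinv_diag) * crossprod(U, r)))
  list(sigma_g2 = sg2, sigma_e2 = se2, lambda = lam, delta = 1 / lam,
       loglik = ll(loglam), beta = beta, u = u,
       eigen_K = list(values = d, vectors = U))
}

#' REML fit of the null mixed model
#'
#' Estimates the genetic and residual variance components of
#' `y = X beta + u + e`, `Var(u) = sigma_g^2 K`, once under the null
#' (no SNP term), by spectral decomposition and one-dimensional REML
#' optimization over the variance ratio.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param K kinship matrix (positive semidefinite).
#' @return list of class `null_model_fit` with `sigma_g2`, `sigma_e2`,
#'   `delta` (= sigma_e2/sigma_g2), `h2`, `loglik`, `beta`, `u`.
#' @export
reml_null <- function(y, X = NULL, K) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  fit <- reml_kernel(y, X, K)
  fit$h2 <- fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2)
  class(fit) <- "null_model_fit"
  fit
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("null mixed model: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' EMMAX-style association scan
#'
#' Per-SNP generalized least squares with the variance structure fixed at the
#' null REML estimate (`V = sigma_g2 K + sigma_e2 I`); Wald t-tests on the SNP
#' dosage coefficient. SNPs are mean-imputed for the scan; monomorphic SNPs
#' give NA rows.
#'
#' @param y phenotype vector.
#' @param X covariate design matrix (with intercept); NULL = intercept only.
#' @param K kinship matrix.
#' @param G genotype matrix (samples x SNPs) or [variant_table()].
#' @param null optional precomputed [reml_null()] fit.
#' @return data.frame: snp, maf, beta, se, p, neg_log10_p.
#' @export
emmax_scan <- function(y, X = NULL, K, G, null = NULL) {
  vt_snps <- NULL
  if (inherits(G, "variant_table")) { vt_snps <- G$snps; G <- genotypes(G) }
  if (is.null(X)) X <- matrix(1, length(y), 1)
  if (is.null(null)) null <- reml_null(y, X, K)
  n <- length(y); q <- ncol(X)
  d <- null$eigen_K$values; U <- null$eigen_K$vectors
  w <- 1 / sqrt(null$sigma_g2 * d + null$sigma_e2)
  Ty <- w * drop(crossprod(U, y))
  TX <- w * crossprod(U, X)
  Wg <- impute_mean(G)
  TG <- w * crossprod(U, Wg)
  qrX <- qr(TX)
  y_r <- qr.resid(qrX, Ty)
  G_r <- qr.resid(qrX, TG)
  gg <- colSums(G_r^2)
  gy <- drop(crossprod(G_r, y_r))
  yy <- sum(y_r^2)
  df <- n - q - 1
  mono <- apply(Wg, 2, var) < .Machine$double.eps | gg < 1e-12
  beta <- gy / gg
  rss <- pmax(yy - beta * gy, 0)
  se <- sqrt(rss / df / gg)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  beta[mono] <- se[mono] <- p[mono] <- NA
  ids <- if (!is.null(vt_snps)) paste(vt_snps$chrom, vt_snps$pos, sep = "_")
         else colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  data.frame(snp = ids, maf = snp_maf(G), beta = beta, se = se, p = p,
             neg_log10_p = -log10(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit a mixed-linear-model GWAS
#'
#' Convenience front end: builds the simple-matching kinship, the first
#' `n_pcs` genotype principal components as fixed covariates, fits the null
#' model by REML, runs the EMMAX-style scan and computes the effective-test
#' significance threshold.
#'
#' @param y phenotype vector (named or aligned with rows of `G`).
#' @param G genotype matrix (samples x SNPs) or [variant_table()].
#' @param n_pcs number of principal-component covariates (default 3).
#' @param K optional kinship matrix (default [smc_kinship()]).
#' @param threshold_override optional working threshold on the -log10(p)
#'   scale; the reported working threshold is the smaller of this and the
#'   effective-test threshold.
#' @return object of class `mlm_gwas`: `results` (per-SNP table), `null`
#'   (variance components), `threshold` (see [significance_threshold()]),
#'   `n_pcs`, call metadata.
#' @export
mlm_gwas <- function(y, G, n_pcs = 3, K = NULL, threshold_override = NULL) {
  Gm <- if (inherits(G, "variant_table")) genotypes(G) else G
  if (is.null(K)) K <- smc_kinship(Gm)
  X <- matrix(1, length(y), 1)
  if (n_pcs > 0) X <- cbind(X, pca_genotypes(Gm, n_pcs)$scores)
  null <- reml_null(y, X, K)
  res <- emmax_scan(y, X, K, G, null = null)
  thr <- significance_threshold(Gm, override = threshold_override)
  structure(list(results = res, null = null, threshold = thr, n_pcs = n_pcs,
                 n = length(y), m = ncol(Gm)),
            class = "mlm_gwas")
}

#' @export
print.mlm_gwas <- function(x, ...) {
  cat("mlm_gwas:", x$m, "SNPs,", x$n, "samples,", x$n_pcs, "PC covariates\n")
  print(x$null)
  cat(sprintf("  effective tests N = %d, threshold -log10(p) = %.2f (working %.2f)\n",
              x$threshold$n_eff, x$threshold$threshold, x$threshold$working))
  cat("  SNPs above working threshold:",
      sum(x$results$neg_log10_p >= x$threshold$working, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.mlm_gwas <- function(object, ...) {
  hits <- object$results[!is.na(object$results$p) &
                           object$results$neg_log10_p >=
                           object$threshold$working, , drop = FALSE]
  hits <- hits[order(hits$p), , drop = FALSE]
  out <- list(hits = hits, threshold = object$threshold, null = object$null,
              lambda_gc = genomic_control_lambda(object$results$p))
  class(out) <- "summary.mlm_gwas"
  out
}

#' @export
print.summary.mlm_gwas <- function(x, ...) {
  cat(sprintf("genomic-control lambda: %.3f\n", x$lambda_gc))
  cat(sprintf("significant SNPs at -log10(p) >= %.2f: %d\n",
              x$threshold$working, nrow(x$hits)))
  if (nrow(x$hits)) print(head(x$hits, 10))
  invisible(x)
}

#' @export
plot.mlm_gwas <- function(x, ...) {
  lp <- x$results$neg_log10_p
  plot(seq_along(lp), lp, pch = 20, cex = 0.5, xlab = "SNP index",
       ylab = expression(-log[10](p)), ...)
  abline(h = x$threshold$working, lty = 2, col = "red")
  invisible(x)
}

#' Genomic-control lambda
#' @param p vector of p-values.
#' @return median chi-squared ratio.
#' @export
genomic_control_lambda <- function(p) {
  chi <- qnorm(p[!is.na(p)] / 2)^2
  median(chi) / qchisq_median1
}
qchisq_median1 <- 0.4549364  # median of chi^2_1

#' Effective-test significance threshold
#'
#' The effective number of independent markers N is the size of the LD-pruned
#' set; the genome-wide threshold is `-log10(1/N) = log10(N)`. A configured
#' working override is applied as `min(threshold, override)`.
#'
#' @param G genotype matrix or [variant_table()].
#' @param prune_r2 pruning r-squared (default 0.1).
#' @param window_snps,step_snps pruning window geometry.
#' @param override optional working threshold.
#' @return list: `n_eff`, `threshold`, `working`.
#' @export
significance_threshold <- function(G, prune_r2 = 0.1, window_snps = 100,
                                   step_snps = 10, override = NULL) {
  kept <- ld_prune(G, window_snps, step_snps, prune_r2)
  n_eff <- length(kept)
  thr <- log10(n_eff)
  list(n_eff = n_eff, threshold = thr,
       working = if (is.null(override)) thr else min(thr, override))
}

#' Trait differences between genotype classes at one SNP
#'
#' Per-class means/medians, a one-way ANOVA F-test, and pairwise Welch t-tests
#' with significance stars (0.05 / 0.01 / 0.001).
#'
#' @param y phenotype vector.
#' @param snp genotype vector (codes 0/1/2/NA) at the locus.
#' @return object of class `genotype_group_test`.
#' @export
genotype_group_test <- function(y, snp) {
  ok <- !is.na(snp) & !is.na(y)
  g <- factor(snp[ok], levels = sort(unique(snp[ok])))
  yv <- y[ok]
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >= 2 genotype classes with >= 2 observations")
  fit <- aov(yv ~ g)
  an <- anova(fit)
  lv <- levels(g)
  pw <- data.frame(a = character(0), b = character(0), p = numeric(0),
                   stars = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    tt <- t.test(yv[g == lv[i]], yv[g == lv[j]])
    pw <- rbind(pw, data.frame(a = lv[i], b = lv[j], p = tt$p.value,
                               stars = p_stars(tt$p.value)))
  }
  structure(list(means = tapply(yv, g, mean), medians = tapply(yv, g, median),
                 n = as.vector(counts), f = an$`F value`[1],
                 p = an$`Pr(>F)`[1], pairwise = pw),
            class = "genotype_group_test")
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.genotype_group_test <- function(x, ...) {
  cat("genotype-class means:\n"); print(round(x$means, 4))
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g\n", x$f, x$p))
  print(x$pairwise)
  invisible(x)
}

# two-locus haplotype-frequency EM from unphased diploid dosages
em_haplotype <- function(g1, g2, max_iter = 200, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NULL)
  # haplotypes: 11 (altA altB), 10, 01, 00
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  tt <- table(factor(g1, 0:2), factor(g2, 0:2))
  n_dh <- tt[2, 2]  # double heterozygotes: phase ambiguous
  # fixed haplotype counts from unambiguous genotypes
  cnt0 <- c(2 * tt[3, 3] + tt[3, 2] + tt[2, 3],        # 11
            2 * tt[3, 1] + tt[3, 2] + tt[2, 1],        # 10
            2 * tt[1, 3] + tt[1, 2] + tt[2, 3],        # 01
            2 * tt[1, 1] + tt[1, 2] + tt[2, 1])        # 00
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    cnt <- cnt0 + n_dh * c(w, 1 - w, 1 - w, w)
    p_new <- cnt / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  list(p = p, pA = pA, pB = pB, n = n)
}

#' Pairwise linkage disequilibrium (r-squared and D')
#'
#' Two-locus haplotype frequencies are estimated by EM from unphased diploid
#' genotypes, then `D`, `D'` and `r^2` derived. Monomorphic SNPs give NA;
#' if the EM degenerates the composite (dosage-correlation) r-squared is used.
#'
#' @param G genotype matrix (samples x SNPs) or [variant_table()], columns in
#'   genomic order.
#' @param idx optional column indices to restrict to (a window).
#' @return list of class `ld_stats` with symmetric matrices `r2` and `dprime`.
#' @export
ld_pairwise <- function(G, idx = NULL) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  if (!is.null(idx)) G <- G[, idx, drop = FALSE]
  m <- ncol(G)
  r2 <- dp <- matrix(NA_real_, m, m, dimnames = list(colnames(G), colnames(G)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    em <- em_haplotype(G[, i], G[, j])
    if (is.null(em)) next
    D <- em$p[1] - em$pA * em$pB
    denom <- em$pA * (1 - em$pA) * em$pB * (1 - em$pB)
    r2v <- if (denom > 0) D^2 / denom else NA_real_
    if (!is.finite(r2v)) {  # composite fallback
      r2v <- suppressWarnings(cor(G[, i], G[, j], use = "complete.obs"))^2
    }
    dmax <- if (D >= 0) min(em$pA * (1 - em$pB), (1 - em$pA) * em$pB)
            else min(em$pA * em$pB, (1 - em$pA) * (1 - em$pB))
    dpv <- if (dmax > 0) abs(D) / dmax else NA_real_
    r2[i, j] <- r2[j, i] <- r2v
    dp[i, j] <- dp[j, i] <- min(dpv, 1)
  }
  structure(list(r2 = r2, dprime = dp), class = "ld_stats")
}

#' Haplotype blocks as runs of high D'
#'
#' Maximal runs of consecutive SNPs whose adjacent-pair D' is at least
#' `dprime_min` (a threshold-run simplification of block calling).
#'
#' @param G genotype matrix or [variant_table()], columns in genomic order.
#' @param dprime_min run threshold (default 0.98).
#' @return data.frame with block `start` and `end` column indices.
#' @export
haplotype_blocks <- function(G, dprime_min = 0.98) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  m <- ncol(G)
  if (m < 2) return(data.frame(start = integer(0), end = integer(0)))
  adj <- vapply(seq_len(m - 1), function(i) {
    em <- em_haplotype(G[, i], G[, i + 1])
    if (is.null(em)) return(NA_real_)
    D <- em$p[1] - em$pA * em$pB
    dmax <- if (D >= 0) min(em$pA * (1 - em$pB), (1 - em$pA) * em$pB)
            else min(em$pA * em$pB, (1 - em$pA) * (1 - em$pB))
    if (dmax > 0) min(abs(D) / dmax, 1) else NA_real_
  }, 0)
  high <- !is.na(adj) & adj >= dprime_min
  blocks <- data.frame(start = integer(0), end = integer(0))
  i <- 1
  while (i <= length(high)) {
    if (high[i]) {
      j <- i
      while (j < length(high) && high[j + 1]) j <- j + 1
      blocks <- rbind(blocks, data.frame(start = i, end = j + 1))
      i <- j + 1
    }
    i <- i + 1
  }
  blocks
}
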