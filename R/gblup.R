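# GBLUP: VanRaden genomic relationship matrix, spectral REML fit of
# y = X beta + Z u + e with Var(u) = sigma_g2 G, BLUP breeding values,
# heritability / predictive-ability / prediction-accuracy arithmetic.

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = M M' / (2 sum p_k (1 - p_k))`, with M the mean-imputed dosage matrix
#' column-centered by `2 p_k`. A ridge of 1e-8 is added to the diagonal so G
#' is numerically positive semidefinite.
#'
#' @param W genotype matrix (samples x SNPs) or [variant_table()];
#'   MAF-filtered markers expected.
#' @return symmetric n x n relationship matrix.
#' @export
vanraden_grm <- function(W) {
  if (inherits(W, "variant_table")) W <- genotypes(W)
  Wi <- impute_mean(W)
  if (all(apply(Wi, 2, var) == 0)) stop("all markers monomorphic: GRM undefined")
  p <- colMeans(Wi) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: GRM undefined")
  M <- sweep(Wi, 2, 2 * p)
  G <- tcrossprod(M) / denom
  G + diag(1e-8, nrow(G))
}

#' Fit a GBLUP model
#'
#' REML variance components of `y = X beta + u + e`, `Var(u) = sigma_g2 K`,
#' by spectral decomposition and one-dimensional optimization of the
#' restricted likelihood over the variance ratio; breeding values from the
#' mixed-model equations; broad-sense heritability as
#' `sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param y phenotype vector.
#' @param K genomic relationship matrix (e.g. [vanraden_grm()]).
#' @param X fixed-effect design matrix (default: intercept only).
#' @return object of class `gblup` with `sigma_g2`, `sigma_e2`, `h2`, `beta`,
#'   `gebv`, `fitted`, `loglik` and prediction state.
#' @export
gblup <- function(y, K, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  fit <- reml_kernel(y, X, K)
  r <- y - drop(X %*% fit$beta)
  d <- fit$eigen_K$values; U <- fit$eigen_K$vectors
  vinv_r <- drop(U %*% (crossprod(U, r) / (fit$sigma_g2 * d + fit$sigma_e2)))
  out <- list(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
              h2 = heritability(fit$sigma_g2, fit$sigma_e2),
              beta = fit$beta, gebv = fit$u,
              fitted = drop(X %*% fit$beta) + fit$u,
              loglik = fit$loglik, y = y, X = X, vinv_r = vinv_r, n = length(y))
  class(out) <- "gblup"
  out
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("gblup fit (n = %d): sigma_g2 = %.4g, sigma_e2 = %.4g, H2 = %.3f\n",
              x$n, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  cat(sprintf("GBLUP REML fit, n = %d\n", object$n))
  cat(sprintf("  variance components: sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              object$sigma_g2, object$sigma_e2))
  cat(sprintf("  broad-sense heritability H2 = %.3f\n", object$h2))
  cat(sprintf("  fixed effects: %s\n",
              paste(signif(object$beta, 4), collapse = ", ")))
  cat(sprintf("  REML log-likelihood: %.3f\n", object$loglik))
  invisible(object)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$y - object$fitted

#' Predict breeding values for new individuals
#'
#' `u_new = sigma_g2 K_cross V^{-1} (y - X beta)` plus the fixed-effect part
#' when a design matrix for the new individuals is supplied.
#'
#' @param object a [gblup()] fit.
#' @param K_cross relationship matrix rows: new individuals x training
#'   individuals.
#' @param X_new optional fixed-effect design for the new individuals.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gblup <- function(object, K_cross, X_new = NULL, ...) {
  u <- object$sigma_g2 * drop(K_cross %*% object$vinv_r)
  if (!is.null(X_new)) u <- u + drop(as.matrix(X_new) %*% object$beta)
  u
}

#' Broad-sense heritability from variance components
#' @param sigma_g2,sigma_e2 genetic and residual variances (>= 0, not both 0).
#' @return `sigma_g2 / (sigma_g2 + sigma_e2)`.
#' @export
heritability <- function(sigma_g2, sigma_e2) {
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0)
  if (sigma_g2 + sigma_e2 == 0) stop("both variance components are zero")
  sigma_g2 / (sigma_g2 + sigma_e2)
}

#' Prediction accuracy from predictive ability and heritability
#' @param pa predictive ability (Pearson correlation of phenotype and GEBV).
#' @param h2 heritability in (0, 1].
#' @return `pa / sqrt(h2)`.
#' @export
prediction_accuracy <- function(pa, h2) {
  if (h2 <= 0) stop("h2 must be positive")
  pa / sqrt(h2)
}

#' Percent improvement between two metric values
#' @param before,after metric values (`before != 0`).
#' @return `100 * (after - before) / before`.
#' @export
improvement_pct <- function(before, after) {
  if (before == 0) stop("before must be nonzero")
  100 * (after - before) / before
}
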