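# R front end for the Bayes-alphabet Gibbs samplers (compiled in src/).

#' Fit a Bayes-alphabet marker-effect model
#'
#' Gibbs sampling for `y = X beta + W a + e` with marker-effect priors:
#' BayesA (per-marker variance, scaled-inverse-chi-square), BayesB (point
#' mass at zero with prior exclusion probability `pi0` plus the BayesA slab),
#' BayesC (point mass plus a common slab variance). Hyperpriors follow the
#' usual heuristic: scaled-inverse-chi-square with `df = 5` and scale chosen
#' so the implied prior genetic variance matches `R2 * var(y)`.
#'
#' @param y phenotype vector.
#' @param W marker dosage matrix (samples x markers); mean-imputed internally.
#' @param X fixed-effect design (default: intercept only).
#' @param model one of "A", "B", "C".
#' @param n_iter,burn_in,thin chain settings (defaults 3000 / 500 / 1,
#'   desk-scale).
#' @param pi0 prior exclusion probability for BayesB/C (default 0.99;
#'   ignored by BayesA).
#' @param R2 assumed proportion of variance captured by markers, used to set
#'   the prior scales (default 0.5).
#' @param df_marker,df_resid prior degrees of freedom (default 5).
#' @param seed mandatory RNG seed: same seed, same chain, bit-for-bit.
#' @return object of class `bayes_gs`: posterior-mean marker effects `a`,
#'   inclusion probabilities, `beta`, `gebv` (= posterior mean of `W a`),
#'   `sigma_e2`, `h2`, settings.
#' @export
bayes_gs <- function(y, W, X = NULL, model = c("C", "A", "B"),
                     n_iter = 3000, burn_in = 500, thin = 1, pi0 = 0.99,
                     R2 = 0.5, df_marker = 5, df_resid = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  model <- match.arg(model)
  stopifnot(n_iter > burn_in)
  if (inherits(W, "variant_table")) W <- genotypes(W)
  W <- impute_mean(W)
  if (is.null(X)) X <- matrix(1, length(y), 1)
  X <- as.matrix(X)
  vy <- var(y)
  sum_var <- sum(apply(W, 2, var))
  if (sum_var <= 0) stop("all markers monomorphic")
  vm <- R2 * vy / sum_var
  if (model %in% c("B", "C")) vm <- vm / (1 - pi0)
  scale_a <- vm * (df_marker - 2) / df_marker
  scale_e <- (1 - R2) * vy * (df_resid - 2) / df_resid
  mcode <- match(model, c("A", "B", "C")) - 1L
  set.seed(seed)
  res <- .bayes_gibbs(y, X, W, mcode, as.integer(n_iter),
                      as.integer(burn_in), as.integer(thin), pi0,
                      df_marker, scale_a, df_resid, scale_e)
  out <- list(model = paste0("Bayes", model), a = res$a,
              inclusion = res$inclusion, beta = res$beta,
              gebv = drop(W %*% res$a), g_hat = res$g,
              sigma_e2 = res$sigma_e2, h2 = res$h2,
              n_iter = n_iter, burn_in = burn_in, thin = thin,
              pi0 = pi0, seed = seed, n = length(y), m = ncol(W))
  class(out) <- "bayes_gs"
  out
}

#' @export
print.bayes_gs <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, m = %d markers, %d iterations (%d burn-in)\n",
              x$model, x$n, x$m, x$n_iter, x$burn_in))
  cat(sprintf("  posterior mean sigma_e2 = %.4g, H2 = %.3f\n",
              x$sigma_e2, x$h2))
  if (x$model != "BayesA")
    cat(sprintf("  mean marker inclusion probability: %.4f\n",
                mean(x$inclusion)))
  invisible(x)
}

#' @export
coef.bayes_gs <- function(object, ...) object$beta

#' Predict genetic values from a Bayes-alphabet fit
#' @param object a [bayes_gs()] fit.
#' @param W_new marker matrix for the new individuals (same marker order).
#' @param X_new optional fixed-effect design for the new individuals.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.bayes_gs <- function(object, W_new, X_new = NULL, ...) {
  W_new <- impute_mean(W_new)
  p <- drop(W_new %*% object$a)
  if (!is.null(X_new)) p <- p + drop(as.matrix(X_new) %*% object$beta)
  p
}
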