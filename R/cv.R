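# Repeated k-fold cross-validation of genomic prediction models, marker-
# density titration and integration of GWAS hits as fixed effects.

#' Append GWAS-hit SNPs to the fixed-effect design
#'
#' The listed markers' dosage columns are appended to X as fixed covariates
#' and removed from the random-effect marker set (avoiding double counting of
#' their variance). Columns collinear with the existing design are dropped
#' with a warning.
#'
#' @param X fixed-effect design matrix (NULL = intercept only).
#' @param W marker dosage matrix (samples x markers).
#' @param snp_idx column indices of the SNPs to promote to fixed effects.
#' @return list with `X` (augmented design), `W` (remaining markers),
#'   `used` (indices actually appended), `dropped` (collinear/monomorphic).
#' @export
integrate_fixed_effect_snps <- function(X, W, snp_idx) {
  if (is.null(X)) X <- matrix(1, nrow(W), 1)
  X <- as.matrix(X)
  if (!length(snp_idx)) return(list(X = X, W = W, used = integer(0),
                                    dropped = integer(0)))
  Wi <- impute_mean(W)
  used <- integer(0); dropped <- integer(0)
  for (k in snp_idx) {
    cand <- cbind(X, Wi[, k])
    if (qr(cand)$rank > qr(X)$rank) {
      X <- cand
      used <- c(used, k)
    } else {
      dropped <- c(dropped, k)
    }
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " collinear/monomorphic fixed-effect SNP(s)")
  if (!length(used) && length(snp_idx))
    stop("all listed fixed-effect SNPs are monomorphic or collinear")
  list(X = X, W = W[, setdiff(seq_len(ncol(W)), snp_idx), drop = FALSE],
       used = used, dropped = dropped)
}

#' Repeated k-fold cross-validation of a genomic prediction model
#'
#' Samples are split into `k` random disjoint folds per repeat; the model is
#' trained on k-1 folds and breeding values predicted for the held-out fold
#' (held-out phenotypes are never seen by the training fit). Predictive
#' ability (PA) is the Pearson correlation between observed phenotypes and
#' predictions in the held-out fold.
#'
#' @param y phenotype vector.
#' @param G marker matrix (samples x markers) or [variant_table()].
#' @param model "gblup", "bayesA", "bayesB" or "bayesC".
#' @param X fixed-effect design (NULL = intercept only).
#' @param fixed_snps optional marker indices integrated as fixed effects via
#'   [integrate_fixed_effect_snps()].
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 10, desk scale; published
#'   protocols often use 100).
#' @param seed RNG seed for the fold partitions (and Bayes chains).
#' @param ... further arguments to [bayes_gs()] (e.g. `n_iter`).
#' @return object of class `cv_result`: `folds` (repeat, fold, pa, n_test),
#'   `mean_pa`, `sd_pa`, `settings`.
#' @export
cross_validate <- function(y, G, model = "gblup", X = NULL,
                           fixed_snps = NULL, k = 5, repeats = 10, seed = 1,
                           ...) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  n <- length(y)
  stopifnot(n >= 2 * k)
  W <- impute_mean(G)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!is.null(fixed_snps) && length(fixed_snps)) {
    aug <- integrate_fixed_effect_snps(X, W, fixed_snps)
    X <- aug$X; W <- aug$W
  }
  Kfull <- if (model == "gblup") vanraden_grm(W) else NULL
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold_of <- sample(rep(seq_len(k), length.out = n))
    for (fold_i in seq_len(k)) {
      test <- which(fold_of == fold_i)
      train <- which(fold_of != fold_i)
      if (model == "gblup") {
        fit <- gblup(y[train], Kfull[train, train, drop = FALSE],
                     X[train, , drop = FALSE])
        pred <- predict(fit, Kfull[test, train, drop = FALSE],
                        X[test, , drop = FALSE])
      } else {
        mcode <- sub("bayes", "", model)
        fit <- bayes_gs(y[train], W[train, , drop = FALSE],
                        X[train, , drop = FALSE], model = mcode,
                        seed = seed * 1000L + rep_i * 10L + fold_i, ...)
        pred <- predict(fit, W[test, , drop = FALSE], X[test, , drop = FALSE])
      }
      pa <- if (sd(pred) == 0 || sd(y[test]) == 0) NA_real_
            else cor(y[test], pred)
      rows[[length(rows) + 1]] <- data.frame(rep = rep_i, fold = fold_i,
                                             pa = pa, n_test = length(test))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds, mean_pa = mean(folds$pa, na.rm = TRUE),
                 sd_pa = sd(folds$pa, na.rm = TRUE),
                 settings = list(model = model, k = k, repeats = repeats,
                                 seed = seed, m = ncol(W),
                                 n_fixed_snps = length(fixed_snps))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("cv_result: %s, %d-fold x %d repeats, m = %d markers\n",
              s$model, s$k, s$repeats, s$m))
  cat(sprintf("  mean PA = %.3f (sd %.3f)\n", x$mean_pa, x$sd_pa))
  invisible(x)
}

#' Marker-density titration
#'
#' Random marker subsets of the requested sizes (without replacement, one per
#' size, reproducible by seed) are each cross-validated.
#'
#' @param y phenotype vector.
#' @param G marker matrix or [variant_table()].
#' @param sizes marker-subset sizes (values > panel size are an error; use
#'   `ncol` for "all").
#' @param seed RNG seed.
#' @param ... further arguments to [cross_validate()].
#' @return named list of `cv_result`, one per size.
#' @export
marker_titration <- function(y, G, sizes, seed = 1, ...) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  m <- ncol(G)
  if (any(sizes > m)) stop("subset size exceeds panel size")
  out <- list()
  for (s in sizes) {
    set.seed(seed + s)
    cols <- if (s == m) seq_len(m) else sort(sample.int(m, s))
    out[[as.character(s)]] <- cross_validate(y, G[, cols, drop = FALSE],
                                             seed = seed, ...)
  }
  out
}
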