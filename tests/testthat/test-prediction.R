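test_that("VanRaden GRM: hand-computed 3x4 case, duplicates, equilibrium diagonal", {
  W <- matrix(c(0, 1, 2,
                2, 1, 0,
                1, 1, 0,
                0, 2, 2), 3, 4)
  p <- colMeans(W) / 2
  M <- sweep(W, 2, 2 * p)
  Ghand <- M %*% t(M) / (2 * sum(p * (1 - p)))
  G <- vanraden_grm(W)
  expect_equal(unname(G), Ghand + diag(1e-8, 3), tolerance = 1e-12)
  # duplicated individuals: identical rows, G_ij = G_ii
  W2 <- rbind(W, W[1, ])
  G2 <- vanraden_grm(W2)
  expect_equal(G2[1, 4], G2[1, 1] - 1e-8, tolerance = 1e-12)
  # independent equilibrium simulation: mean diagonal near 1
  set.seed(17)
  W3 <- matrix(rbinom(200 * 1000, 2, rep(runif(1000, 0.1, 0.9), each = 200)),
               200, 1000)
  expect_lt(abs(mean(diag(vanraden_grm(W3))) - 1), 0.05)
  expect_error(vanraden_grm(matrix(1, 5, 3)), "monomorphic")
})

test_that("GBLUP limits: noise-free traits give H2 near 1, noise gives near 0", {
  sim <- make_sim(seed = 27, n_samples = 150, n_snps = 800, n_subpops = 1,
                  fst = 0, missing_rate = 0)
  K <- vanraden_grm(sim$vt)
  ph <- simulate_phenotype(sim$vt, n_qtn = 100, h2_target = 1, seed = 2)
  expect_gte(gblup(ph$y, K)$h2, 0.98)
  # null: a well-powered design (n >> m) keeps the boundary estimate near 0
  sim0 <- make_sim(seed = 29, n_samples = 400, n_snps = 200, n_subpops = 1,
                   fst = 0, missing_rate = 0)
  K0 <- vanraden_grm(sim0$vt)
  h2s <- vapply(1:10, function(s) {
    set.seed(700 + s)
    gblup(rnorm(400), K0)$h2
  }, 0)
  expect_lte(mean(h2s), 0.05)
})

test_that("GBLUP GEBVs equal ridge-regression marker predictions (RR-BLUP)", {
  for (seed in c(37, 38)) {
    sim <- make_sim(seed = seed, n_samples = 80, n_snps = 400,
                    missing_rate = 0.03)
    ph <- simulate_phenotype(sim$vt, n_qtn = 40, h2_target = 0.5, seed = 1)
    W <- panelcraft:::impute_mean(genotypes(sim$vt))
    p <- colMeans(W) / 2
    cnorm <- 2 * sum(p * (1 - p))
    M <- sweep(W, 2, 2 * p)
    K <- vanraden_grm(sim$vt)
    fit <- gblup(ph$y, K)
    lam <- fit$sigma_e2 / fit$sigma_g2 * cnorm
    r <- ph$y - drop(fit$X %*% fit$beta)
    a_hat <- solve(crossprod(M) + diag(lam, ncol(M)), crossprod(M, r))
    expect_lt(max(abs(fit$gebv - drop(M %*% a_hat))), 1e-6)
  }
})

test_that("gblup methods: coef, fitted, residuals, predict self-consistency", {
  sim <- make_sim(seed = 47, n_samples = 60, n_snps = 300, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = 30, h2_target = 0.6, seed = 3)
  K <- vanraden_grm(sim$vt)
  fit <- gblup(ph$y, K)
  expect_length(coef(fit), 1)
  expect_equal(fitted(fit) + residuals(fit), unname(ph$y), tolerance = 1e-10,
               ignore_attr = TRUE)
  # predicting the training individuals reproduces their GEBVs
  expect_equal(unname(predict(fit, K)), unname(fit$gebv), tolerance = 1e-8)
  expect_equal(fit$h2, heritability(fit$sigma_g2, fit$sigma_e2))
})

test_that("Bayes samplers are seed-deterministic", {
  sim <- make_sim(seed = 57, n_samples = 50, n_snps = 150, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = 10, h2_target = 0.5, seed = 4)
  W <- genotypes(sim$vt)
  for (m in c("A", "B", "C")) {
    f1 <- bayes_gs(ph$y, W, model = m, n_iter = 300, burn_in = 100, seed = 9)
    f2 <- bayes_gs(ph$y, W, model = m, n_iter = 300, burn_in = 100, seed = 9)
    expect_identical(f1$gebv, f2$gebv)
    expect_identical(f1$a, f2$a)
    f3 <- bayes_gs(ph$y, W, model = m, n_iter = 300, burn_in = 100, seed = 10)
    expect_false(identical(f1$gebv, f3$gebv))
  }
})

test_that("BayesB/C posterior inclusion concentrates on true large QTN", {
  sim <- make_sim(seed = 67, n_samples = 300, n_snps = 505, n_subpops = 1,
                  fst = 0, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = 5, h2_target = 0.6, seed = 5)
  W <- genotypes(sim$vt)
  for (m in c("B", "C")) {
    fit <- bayes_gs(ph$y, W, model = m, n_iter = 3000, burn_in = 500,
                    seed = 11)
    qtn_in <- mean(fit$inclusion[ph$truth$qtn])
    bg_in <- mean(fit$inclusion[-ph$truth$qtn])
    expect_gt(qtn_in, 10 * bg_in)
  }
})

test_that("BayesC with near-zero exclusion degenerates toward GBLUP", {
  sim <- make_sim(seed = 77, n_samples = 100, n_snps = 400, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = 100, h2_target = 0.5, seed = 6)
  W <- genotypes(sim$vt)
  bf <- bayes_gs(ph$y, W, model = "C", pi0 = 0.001, n_iter = 1500,
                 burn_in = 300, seed = 12)
  gf <- gblup(ph$y, vanraden_grm(W))
  expect_gt(cor(bf$gebv, gf$gebv), 0.95)
})

test_that("cross-validation limits: heritable traits predict, noise does not", {
  # noise-free polygenic trait with n >> m: marker effects are estimable and
  # held-out predictions approach the phenotype
  sim <- make_sim(seed = 87, n_samples = 300, n_snps = 150, n_subpops = 1,
                  fst = 0, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = NULL, h2_target = 1, seed = 7)
  cv1 <- cross_validate(ph$y, sim$vt, model = "gblup", k = 5, repeats = 2,
                        seed = 1)
  expect_gt(cv1$mean_pa, 0.9)
  ph0 <- simulate_phenotype(sim$vt, n_qtn = NULL, h2_target = 0, seed = 8)
  cv0 <- cross_validate(ph0$y, sim$vt, model = "gblup", k = 5, repeats = 4,
                        seed = 2)
  expect_lt(abs(cv0$mean_pa), 0.1)
  expect_equal(nrow(cv1$folds), 10)
  # fold partition is a disjoint cover
  expect_equal(sum(cv1$folds$n_test[1:5]), 300)
})

test_that("held-out phenotypes never influence the training fit", {
  sim <- make_sim(seed = 97, n_samples = 100, n_snps = 400, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = 50, h2_target = 0.5, seed = 9)
  K <- vanraden_grm(sim$vt)
  test_idx <- 1:20; train_idx <- 21:100
  y1 <- ph$y
  y2 <- ph$y
  y2[test_idx] <- y2[test_idx] + 100  # poison the held-out labels
  f1 <- gblup(y1[train_idx], K[train_idx, train_idx])
  f2 <- gblup(y2[train_idx], K[train_idx, train_idx])
  expect_identical(f1$sigma_g2, f2$sigma_g2)
  p1 <- predict(f1, K[test_idx, train_idx])
  p2 <- predict(f2, K[test_idx, train_idx])
  expect_identical(p1, p2)
})

test_that("marker titration: identity at full size, reproducible subsets", {
  sim <- make_sim(seed = 18, n_samples = 120, n_snps = 500, n_subpops = 1,
                  fst = 0, missing_rate = 0)
  ph <- simulate_phenotype(sim$vt, n_qtn = 100, h2_target = 0.6, seed = 10)
  t1 <- marker_titration(ph$y, sim$vt, sizes = c(50, 500), seed = 3,
                         model = "gblup", k = 5, repeats = 2)
  t2 <- marker_titration(ph$y, sim$vt, sizes = c(50, 500), seed = 3,
                         model = "gblup", k = 5, repeats = 2)
  expect_equal(t1[["50"]]$mean_pa, t2[["50"]]$mean_pa)
  full <- cross_validate(ph$y, sim$vt, model = "gblup", k = 5, repeats = 2,
                         seed = 3)
  expect_equal(t1[["500"]]$mean_pa, full$mean_pa)
  # monotone-plateau: a small panel does no better than the full one
  expect_lte(t1[["50"]]$mean_pa, t1[["500"]]$mean_pa + 2 * t1[["500"]]$sd_pa)
  expect_error(marker_titration(ph$y, sim$vt, sizes = 600, seed = 1), "exceeds")
})

test_that("fixed-effect SNP integration bookkeeping", {
  sim <- make_sim(seed = 28, n_samples = 80, n_snps = 200, missing_rate = 0)
  W <- genotypes(sim$vt)
  X <- matrix(1, 80, 1)
  aug0 <- integrate_fixed_effect_snps(X, W, integer(0))
  expect_identical(aug0$X, X)
  expect_identical(dim(aug0$W), dim(W))
  aug <- integrate_fixed_effect_snps(X, W, c(5, 10))
  expect_equal(ncol(aug$X), 3)
  expect_equal(ncol(aug$W), 198)
  # a duplicated (collinear) column is dropped with a warning
  W2 <- W
  W2[, 11] <- W2[, 10]
  expect_warning(aug2 <- integrate_fixed_effect_snps(X, W2, c(10, 11)),
                 "collinear")
  expect_equal(aug2$used, 10)
  suppressWarnings(
    expect_error(integrate_fixed_effect_snps(X, matrix(1, 80, 4), 2),
                 "monomorphic or collinear"))
})

test_that("heritability / PA / PC arithmetic and the printed-pair inversion", {
  expect_equal(heritability(1, 1), 0.5)
  expect_equal(heritability(0, 1), 0)
  expect_equal(heritability(3, 1), 0.75)
  expect_error(heritability(0, 0), "zero")
  expect_equal(prediction_accuracy(0.3, 1), 0.3)
  expect_error(prediction_accuracy(0.3, 0), "positive")
  # inverting a printed PA/PC pair and forward-checking it
  h2_implied <- (0.184 / 0.362)^2
  expect_equal(round(prediction_accuracy(0.184, h2_implied), 2), 0.36)
  expect_equal(improvement_pct(2, 3), 50)
  expect_error(improvement_pct(0, 1), "nonzero")
  # PC * sqrt(H2) = PA wherever computed
  for (pa in c(0.1, 0.4)) for (h2 in c(0.25, 0.9)) {
    expect_equal(prediction_accuracy(pa, h2) * sqrt(h2), pa,
                 tolerance = 1e-12)
  }
})
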