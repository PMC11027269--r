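test_that("GBLUP with identity kinship shrinks by the variance-ratio factor", {
  y <- with_seed_test(1, rnorm(40, 5, 2))
  K <- diag(40)
  vc <- list(sigma2_u = 2, sigma2_e = 1)
  fit <- gblup_fit(y, K, vc = vc, ridge = 0)
  mu <- mean(y)  # GLS intercept equals the plain mean when K = I
  expect_lt(abs(fit$mu - mu), 1e-8)
  expect_lt(max(abs(fit$u_hat - 2 / (2 + 1) * (y - mu))), 1e-8)
})

test_that("GBLUP solves the Henderson mixed-model equations", {
  g <- tiny_geno(30, 80, seed = 2)
  K <- compute_kinship(g)$K + 0.01 * diag(30)  # invertible for the MME oracle
  y <- with_seed_test(2, as.vector(g$values[, 1:3] %*% c(1, -1, 0.5)) + rnorm(30))
  vc <- list(sigma2_u = 1.3, sigma2_e = 0.7)
  fit <- gblup_fit(y, K, vc = vc, ridge = 0)
  oc <- oracle_mme(y, K, vc$sigma2_u, vc$sigma2_e)
  expect_lt(abs(fit$mu - oc$mu), 1e-6)
  expect_lt(max(abs(fit$u_hat - oc$u)), 1e-6)
})

test_that("kinship-form GBLUP equals ridge regression on centered markers", {
  g <- tiny_geno(120, 300, seed = 3)
  sim <- simulate_multienv(g, nqtn = 15, h2 = 0.6, seed = 4)
  y_all <- mean_phenotype(sim$phenotypes)
  y <- y_all
  test <- 101:120
  y[test] <- NA
  Z <- sweep(g$values, 2, colMeans(g$values))
  cc <- sum(Z^2) / nrow(Z)
  K <- tcrossprod(Z) / cc
  sigma2_e <- 0.4
  sigma2_beta <- 0.002
  sigma2_u <- cc * sigma2_beta
  fit <- gblup_fit(y, K, vc = list(sigma2_u = sigma2_u, sigma2_e = sigma2_e),
                   ridge = 0)
  beta <- oracle_ridge(Z[-test, , drop = FALSE], y[-test] - fit$mu,
                       sigma2_e / sigma2_beta)
  pred_ridge <- fit$mu + as.vector(Z %*% beta)
  expect_lt(max(abs(predict(fit) - pred_ridge)), 1e-6)
})

test_that("REML and ML variance searches both return a usable optimum", {
  g <- tiny_geno(100, 150, seed = 5)
  K <- compute_kinship(g)$K
  sim <- simulate_multienv(g, nqtn = 20, h2 = 0.7, seed = 6)
  y <- mean_phenotype(sim$phenotypes)
  y[1:20] <- NA
  fr <- gblup_fit(y, K, method = "REML")
  fm <- gblup_fit(y, K, method = "ML")
  expect_gt(fr$sigma2_u, 0)
  expect_gt(fm$sigma2_u, 0)
  # both should predict the held-out phenotypes far better than chance
  expect_gt(cor(predict(fr)[1:20], mean_phenotype(sim$phenotypes)[1:20]), 0.3)
  expect_gt(cor(predict(fm)[1:20], mean_phenotype(sim$phenotypes)[1:20]), 0.3)
})

test_that("clamped-variance BRR matches the conjugate ridge solution", {
  n <- 80; m <- 40
  g <- tiny_geno(n, m, seed = 7)
  X <- g$values
  y <- with_seed_test(3, as.vector(X[, 1:4] %*% c(0.6, -0.6, 0.4, -0.4)) + rnorm(n))
  s2b <- 0.05; s2e <- 1
  fit <- gibbs_fit(y, X, model = "BRR", niter = 6000, burnin = 1000, seed = 8,
                   fixed = list(sigma2_beta = s2b, sigma2_e = s2e))
  Z <- sweep(X, 2, colMeans(X))
  beta_ridge <- oracle_ridge(Z, y - mean(y), s2e / s2b)
  # batch-means Monte Carlo SE per marker from the stored draws is not kept;
  # use a conservative analytic bound: posterior SDs / sqrt(effective draws)
  mcse <- fit$beta_sd[[1]] / sqrt(5000 / 25)
  expect_true(all(abs(fit$beta_mean[[1]] - beta_ridge) < 3 * pmax(mcse, 1e-4)))
})

test_that("BayesB with full inclusion reduces to BayesA", {
  n <- 80; m <- 50
  g <- tiny_geno(n, m, seed = 9)
  sim <- simulate_multienv(g, nqtn = 8, h2 = 0.7, seed = 10)
  y <- sim$phenotypes$values[, 1]
  fa <- gibbs_fit(y, g$values, model = "BayesA", niter = 4000, burnin = 1000,
                  seed = 11)
  fb <- gibbs_fit(y, g$values, model = "BayesB", niter = 4000, burnin = 1000,
                  seed = 12, pi0 = 1)
  pa <- predict_gebv(fa, g$values)
  pb <- predict_gebv(fb, g$values)
  expect_gt(cor(pa, pb), 0.98)
  expect_lt(mean(abs(pa - pb)), 0.15 * sd(pa))
})

test_that("a pure-noise trait yields effects consistent with zero", {
  n <- 80; m <- 40
  g <- tiny_geno(n, m, seed = 13)
  y <- with_seed_test(4, rnorm(n))
  fit <- gibbs_fit(y, g$values, model = "BRR", niter = 3000, burnin = 500,
                   seed = 14)
  z <- abs(fit$beta_mean[[1]]) / pmax(fit$beta_sd[[1]], 1e-12)
  expect_gte(mean(z < 3), 0.95)
})

test_that("Gibbs chains are exactly reproducible and correctly sized", {
  g <- tiny_geno(40, 20, seed = 15)
  y <- with_seed_test(5, rnorm(40))
  f1 <- gibbs_fit(y, g$values, model = "BayesCpi", niter = 400, burnin = 100,
                  thin = 2, seed = 16)
  f2 <- gibbs_fit(y, g$values, model = "BayesCpi", niter = 400, burnin = 100,
                  thin = 2, seed = 16)
  expect_identical(f1$beta_mean, f2$beta_mean)
  expect_identical(f1$chains, f2$chains)
  expect_equal(nrow(f1$chains), (400 - 100) / 2)
  expect_true(all(f1$chains$pi >= 0 & f1$chains$pi <= 1))
  expect_error(gibbs_fit(y, g$values, niter = 100, burnin = 100), "exceed")
})

test_that("all five Bayesian models learn a strongly heritable trait", {
  g <- tiny_geno(100, 60, seed = 17)
  sim <- simulate_multienv(g, nqtn = 10, h2 = 0.8, seed = 18)
  y <- sim$phenotypes$values[, 1]
  for (model in c("BRR", "BayesA", "BayesB", "BayesCpi", "BL")) {
    fit <- gibbs_fit(y, g$values, model = model, niter = 1200, burnin = 400,
                     seed = 19)
    expect_gt(cor(predict_gebv(fit, g$values), y), 0.5)
  }
})

test_that("an all-zero interactive block leaves two-block BRR at the single-block fit", {
  g <- tiny_geno(60, 40, seed = 20)
  sim <- simulate_multienv(g, nqtn = 8, h2 = 0.7, seed = 21)
  y <- sim$phenotypes$values[, 1]
  zero_block <- matrix(0, 60, 40)
  f2 <- gibbs_fit(y, list(g$values, zero_block), model = "BRR",
                  niter = 3000, burnin = 500, seed = 22)
  f1 <- gibbs_fit(y, list(g$values), model = "BRR",
                  niter = 3000, burnin = 500, seed = 22)
  expect_true(all(f2$beta_mean[[2]] == 0))
  p1 <- predict_gebv(f1, list(g$values))
  p2 <- predict_gebv(f2, list(g$values, zero_block))
  expect_gt(cor(p1, p2), 0.99)
})

test_that("gEBV prediction applies intercept plus centered marker effects", {
  fit <- structure(list(mu = 2, beta_mean = list(c(0, 0)),
                        centers = list(c(1, 1))), class = "gibbs_fit")
  X <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
  expect_equal(predict_gebv(fit, X), rep(2, 3))
  fit$beta_mean <- list(c(1, 0))
  expect_equal(predict_gebv(fit, X), 2 + (X[, 1] - 1))
  expect_error(predict_gebv(fit, X[, 1, drop = FALSE]), "columns")
})

test_that("prediction accuracy is a guarded Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(accuracy(x, x)$r, 1)
  expect_equal(accuracy(x, -x)$r, -1)
  y <- c(2, 1, 4, 3)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(accuracy(x, y)$r - manual), 1e-12)
  expect_false(accuracy(c(1, 2), c(1, 2))$defined)       # too few pairs
  expect_false(accuracy(c(1, 1, 1), c(1, 2, 3))$defined) # zero variance
})
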