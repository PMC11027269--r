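test_that("kinship equals the centered cross-product oracle with unit mean diagonal", {
  X <- tiny_geno(30, 80, seed = 1)$values
  K <- compute_kinship(X)
  Z <- sweep(X, 2, colMeans(X))
  K_oracle <- Z %*% t(Z) / (sum(Z^2) / nrow(X))
  expect_lt(max(abs(K$K - K_oracle)), 1e-10)
  expect_equal(mean(diag(K$K)), 1)
  expect_lt(max(abs(K$K - t(K$K))), 1e-12)
  # identical individuals share their diagonal entry off-diagonally
  X2 <- rbind(X[1, ], X)
  K2 <- compute_kinship(X2)$K
  expect_equal(K2[1, 2], K2[1, 1])
  expect_error(compute_kinship(matrix(1, 4, 3)), "zero variance")
})

test_that("expanded-genotype kinship ties environment copies of an individual", {
  g <- tiny_geno(40, 150, seed = 2)
  gb <- expand_genotypes(g, 2)
  K <- compute_kinship(gb)$K
  expect_equal(dim(K), c(80, 80))
  self_pairs <- K[cbind(1:40, 41:80)]
  off <- K[upper.tri(K)]
  expect_gt(mean(self_pairs), mean(off))
})

test_that("principal components match the eigendecomposition oracle up to sign", {
  X <- tiny_geno(25, 60, seed = 3)$values
  S <- compute_pcs(X, 3)
  expect_equal(ncol(S), 3L)
  expect_lt(max(abs(crossprod(S) - diag(diag(crossprod(S))))), 1e-8)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    d <- min(max(abs(S[, j] - pr$x[, j])), max(abs(S[, j] + pr$x[, j])))
    expect_lt(d, 1e-8)
  }
  expect_error(compute_pcs(X, 25), "smaller")
})

test_that("REML delta maximizes the dense profiled restricted likelihood", {
  set.seed(10)
  g <- tiny_geno(80, 120, seed = 4)
  K <- compute_kinship(g)$K
  sim <- simulate_multienv(g, nqtn = 10, h2 = 0.6, seed = 5)
  y <- mean_phenotype(sim$phenotypes)
  W <- cbind(1, compute_pcs(g, 2))
  fit <- fit_null_reml(y, W[, -1], K)
  ll <- function(d) oracle_reml_profile(d, y, W, K)
  expect_gte(ll(fit$delta) + 1e-6, ll(fit$delta * 0.5))
  expect_gte(ll(fit$delta) + 1e-6, ll(fit$delta * 2))
  expect_gte(fit$sigma2_g, 0)
  expect_gt(fit$sigma2_e, 0)
})

test_that("REML recovers a null genetic variance and a strong genetic signal", {
  g <- tiny_geno(200, 150, seed = 6)
  K <- compute_kinship(g)$K
  ratios <- vapply(1:8, function(i) {
    y <- with_seed_test(i, rnorm(200))
    f <- fit_null_reml(y, NULL, K)
    f$sigma2_g / f$sigma2_e
  }, numeric(1))
  expect_lt(mean(ratios), 0.05)
  deltas <- vapply(1:5, function(i) {
    sim <- simulate_multienv(g, nqtn = 50, h2 = 0.9, seed = 50 + i)
    fit_null_reml(sim$phenotypes$values[, 1], NULL, K)$delta
  }, numeric(1))
  expect_lt(mean(deltas), 0.25)
})

test_that("mixed-model scan matches the dense GLS oracle marker by marker", {
  g <- tiny_geno(50, 120, seed = 7)
  K <- compute_kinship(g)$K
  sim <- simulate_multienv(g, nqtn = 5, h2 = 0.5, seed = 8)
  y <- mean_phenotype(sim$phenotypes)
  W0 <- compute_pcs(g, 2)
  nullfit <- fit_null_reml(y, W0, K)
  vc <- list(sigma2_g = nullfit$sigma2_g, sigma2_e = nullfit$sigma2_e)
  markers <- g$values[, 1:5]
  res <- mlm_scan(y, markers, covariates = W0, K = K, vc = vc)
  for (j in 1:5) {
    oc <- oracle_gls(y, markers[, j], cbind(1, W0), K,
                     vc$sigma2_g, vc$sigma2_e)
    expect_lt(abs(res$beta[j] - oc$beta), 1e-6)
    expect_lt(abs(res$se[j] - oc$se), 1e-6)
    expect_lt(abs(res$p[j] - oc$p), 1e-6)
  }
})

test_that("zero genetic variance reduces the scan to OLS t-tests", {
  g <- tiny_geno(40, 30, seed = 9)
  y <- with_seed_test(1, rnorm(40) + g$values[, 3])
  res <- mlm_scan(y, g$values, K = compute_kinship(g)$K,
                  vc = list(sigma2_g = 0, sigma2_e = 1))
  for (j in c(1, 3, 10)) {
    ols <- summary(lm(y ~ g$values[, j]))$coefficients
    expect_lt(abs(res$beta[j] - ols[2, 1]), 1e-8)
    expect_lt(abs(res$p[j] - ols[2, 4]), 1e-8)
  }
})

test_that("jointly permuting rows leaves scan p-values unchanged", {
  g <- tiny_geno(60, 50, seed = 10)
  K <- compute_kinship(g)$K
  sim <- simulate_multienv(g, nqtn = 5, h2 = 0.5, seed = 11)
  y <- mean_phenotype(sim$phenotypes)
  pcs <- compute_pcs(g, 2)
  nullfit <- fit_null_reml(y, pcs, K)
  vc <- list(sigma2_g = nullfit$sigma2_g, sigma2_e = nullfit$sigma2_e)
  r1 <- mlm_scan(y, g$values, covariates = pcs, K = K, vc = vc)
  pp <- with_seed_test(2, sample(60))
  r2 <- mlm_scan(y[pp], g$values[pp, ], covariates = pcs[pp, ],
                 K = K[pp, pp], vc = vc)
  expect_lt(max(abs(r1$p - r2$p)), 1e-10)
  # the REML step itself is permutation-stable to optimizer precision
  nf2 <- fit_null_reml(y[pp], pcs[pp, ], K[pp, pp])
  expect_lt(abs(log(nf2$delta) - log(nullfit$delta)), 1e-4)
})

test_that("P3D and exact per-marker REML agree on moderate data", {
  g <- tiny_geno(100, 40, seed = 12)
  K <- compute_kinship(g)$K
  sim <- simulate_multienv(g, nqtn = 5, h2 = 0.5, seed = 13)
  y <- mean_phenotype(sim$phenotypes)
  r_p3d <- mlm_scan(y, g$values, K = K, p3d = TRUE)
  r_ex <- mlm_scan(y, g$values, K = K, p3d = FALSE)
  dlp <- abs(-log10(r_p3d$p) + log10(r_ex$p))
  expect_gte(mean(dlp <= 0.2), 0.95)
})

test_that("monomorphic markers are skipped with p = 1 and a flag", {
  X <- cbind(m1 = rep(2, 20), m2 = rbinom(20, 2, 0.4))
  X[1, 2] <- 1  # ensure polymorphic
  y <- rnorm(20)
  res <- mlm_scan(y, X, K = NULL)
  expect_equal(res$p[1], 1)
  expect_equal(res$skipped[1], "monomorphic")
  expect_equal(res$skipped[2], "")
})

test_that("interactive tests raise no false signal when environments are identical", {
  # r = 1 effects and a residual shared across environments: the two
  # environment columns are identical, so interactive copies carry no
  # signal; duplicated residuals make the t-test conservative there, so the
  # check is one-sided — small p-values must not exceed their nominal rate
  pvals <- unlist(lapply(1:8, function(i) {
    g <- tiny_geno(100, 80, seed = 20 + i)
    q <- sample_qtn(g, 10, seed = i)
    eff <- sample_effects(10, 2, r = 1, seed = i)
    gv <- g$values[, q, drop = FALSE] %*% eff
    noise <- with_seed_test(300 + i,
                            rnorm(100, 0, sqrt(var(gv[, 1]) * 0.5 / 0.5)))
    ph <- pheno_table(gv + noise, g$individual_ids)
    res <- gwas_scan(g, ph, mode = "gbye")
    res$p[res$effect_class != "additive" & res$skipped == ""]
  }))
  nominal <- 0.05
  slack <- 2.576 * sqrt(nominal * (1 - nominal) / length(pvals))
  expect_lte(mean(pvals < nominal), nominal + slack)
  expect_lte(mean(pvals < 0.01), 0.01 + 2.576 * sqrt(0.01 * 0.99 / length(pvals)))
})

test_that("p-value collapsing keeps the winning copy and applies the Bonferroni cap", {
  res <- data.frame(marker_id = c("a", "b", "a", "b"),
                    effect_class = c("additive", "additive",
                                     "interactive:env2", "interactive:env2"),
                    p = c(0.01, 0.9, 0.5, 0.9))
  mn <- collapse_pvalues(res, "min")
  expect_equal(mn$p, c(0.01, 0.9))
  expect_equal(mn$effect_class[1], "additive")
  expect_equal(mn$n_copies, c(2L, 2L))
  bf <- collapse_pvalues(res, "bonf-min")
  expect_equal(bf$p, c(0.02, 1))  # x2, capped at 1
  expect_error(collapse_pvalues(data.frame(x = 1)), "marker_id")
})
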