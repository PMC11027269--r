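#' GBLUP fit with kinship-based prediction of masked individuals
#'
#' Solves `y = 1 mu + u + e`, `u ~ N(0, sigma2_u K)`, on the rows where `y`
#' is observed, estimating the variance ratio by REML (default) or full ML
#' through a one-dimensional spectral search. Breeding values for all rows —
#' including masked ones — come from the kinship cross-block:
#' `u = K[, train] (K[train, train] + delta I)^{-1} (y_train - mu)`. With a
#' kinship proportional to the centered marker cross-product this is the
#' ridge-regression ("rrBLUP") predictor expressed in kinship form.
#'
#' @param y numeric vector over all N rows; `NA` marks masked entries.
#' @param K N x N kinship (matrix or [compute_kinship()] result) covering
#'   train and test rows.
#' @param method `"REML"` or `"ML"` variance-component estimation.
#' @param vc optional list `(sigma2_u, sigma2_e)` to use as-is (no
#'   estimation); used by equivalence oracles.
#' @param ridge numerical floor added to the training kinship diagonal.
#' @return list of class `gblup_fit`: `mu`, `u_hat` (length N), `sigma2_u`,
#'   `sigma2_e`, `delta`, `method`, `train` (row indices), `loglik`.
#' @export
gblup_fit <- function(y, K, method = c("REML", "ML"), vc = NULL,
                      ridge = 1e-6) {
  method <- match.arg(method)
  if (inherits(K, "kinship")) K <- K$K
  N <- length(y)
  if (nrow(K) != N) stopf("kinship dimension != length(y)")
  train <- which(!is.na(y))
  if (length(train) < 3L) stopf("need at least 3 observed phenotypes")
  Kt <- K[train, train, drop = FALSE]
  diag(Kt) <- diag(Kt) + ridge
  yt <- y[train]
  n <- length(train)
  ee <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  if (max(lam) <= 0) stopf("training kinship is singular after the ridge floor")
  U <- ee$vectors
  eta <- as.vector(crossprod(U, yt))
  w <- as.vector(crossprod(U, rep(1, n)))

  ml_loglik <- function(delta) {
    d <- 1 / (lam + delta)
    mu <- sum(w * d * eta) / sum(w^2 * d)
    s2 <- sum(d * (eta - w * mu)^2) / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(lam + delta)) + n)
  }

  if (!is.null(vc)) {
    sigma2_u <- vc$sigma2_u; sigma2_e <- vc$sigma2_e
    delta <- sigma2_e / sigma2_u
    ll <- NA_real_
  } else if (method == "REML") {
    fit <- fit_null_reml(yt, NULL, Kt)
    sigma2_u <- fit$sigma2_g; sigma2_e <- fit$sigma2_e
    delta <- fit$delta; ll <- fit$loglik
  } else {
    grid <- exp(seq(log(1e-5), log(1e5), length.out = 61))
    lls <- vapply(grid, ml_loglik, numeric(1))
    i <- which.max(lls)
    opt <- stats::optimize(function(ld) ml_loglik(10^ld),
                           interval = log10(c(grid[max(i - 1L, 1L)],
                                              grid[min(i + 1L, length(grid))])),
                           maximum = TRUE, tol = 1e-8)
    delta <- 10^opt$maximum; ll <- opt$objective
    d <- 1 / (lam + delta)
    mu0 <- sum(w * d * eta) / sum(w^2 * d)
    sigma2_u <- sum(d * (eta - w * mu0)^2) / n
    sigma2_e <- delta * sigma2_u
  }

  d <- 1 / (lam + delta)
  mu <- sum(w * d * eta) / sum(w^2 * d)
  alpha <- U %*% (d * (eta - w * mu))
  u_hat <- as.vector(K[, train, drop = FALSE] %*% alpha)
  structure(list(mu = mu, u_hat = u_hat, sigma2_u = sigma2_u,
                 sigma2_e = sigma2_e, delta = delta, method = method,
                 train = train, loglik = ll),
            class = "gblup_fit")
}

#' @export
predict.gblup_fit <- function(object, ...) object$mu + object$u_hat

# BGLR-style prior scales from the R2 rule: apportion a target model R2
# across blocks, scale variance priors so the prior-mode genetic variance
# matches that share of var(y)
gibbs_hyper <- function(y, xx_blocks, R2, df0, dfe, n) {
  vy <- stats::var(y)
  nb <- length(xx_blocks)
  r2b <- R2 / nb
  S0 <- lapply(xx_blocks, function(xx) {
    msx <- sum(xx) / n
    if (msx <= 0) return(1e-10)
    vy * r2b / msx * (df0 + 2)
  })
  lambda2 <- lapply(xx_blocks, function(xx) {
    msx <- sum(xx) / n
    if (msx <= 0) return(1)
    2 * (1 - r2b) * msx / r2b
  })
  list(S0 = S0, lambda2 = lambda2, Se = vy * (1 - R2) * (dfe + 2), vy = vy)
}

#' Gibbs-sampled whole-genome regression with effect blocks
#'
#' Bayesian marker regression `y = mu + sum_b X_b beta_b + e` fit by Gibbs
#' sampling, with the markers organized in blocks (for the expanded
#' genotype: one additive block and one interactive block, the two "ETA"
#' entries of the original workflow). Priors per model:
#' \describe{
#'   \item{BRR}{one Gaussian variance per block, scaled-inv-chi-square
#'     hyperprior.}
#'   \item{BayesA}{marker-specific scaled-t variances.}
#'   \item{BayesB}{point-mass/slab mixture with fixed inclusion probability
#'     `pi0` and marker-specific slab variances.}
#'   \item{BayesCpi}{point-mass/slab with one common slab variance per block
#'     and Beta(1,1)-updated inclusion probability.}
#'   \item{BL}{Bayesian LASSO: double-exponential effects via per-marker
#'     exponential variance mixing.}
#' }
#' Variance-prior scales follow the R2 rule (prior-mode genetic variance =
#' `R2 x var(y)`, split evenly across blocks).
#'
#' @param y training response (complete; subset masked rows out first).
#' @param X_blocks list of marker matrices (rows aligned to `y`), or one
#'   matrix; columns are centered internally and the centers stored.
#' @param model `"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesCpi"` or `"BL"`.
#' @param niter,burnin,thin chain controls; defaults (1500/500/1) are
#'   desk-scale — raise towards 12000/10000 for production runs.
#' @param seed integer seed; chains are exactly reproducible given
#'   (seed, niter, burnin, thin).
#' @param pi0 slab inclusion probability (BayesB fixed; BayesCpi initial).
#' @param R2,df0,dfe hyper-prior controls of the R2 rule.
#' @param fixed optional list clamping variances instead of sampling them:
#'   `sigma2_beta` (per block, recycled) and/or `sigma2_e`.
#' @return list of class `gibbs_fit`: `mu` (posterior mean), `beta_mean` and
#'   `beta_sd` (lists per block), `centers` (list per block), `chains` (data.frame of
#'   sigma2_e, per-block variances, pi), `model`, `niter`, `burnin`,
#'   `thin`, `seed`.
#' @export
gibbs_fit <- function(y, X_blocks, model = c("BRR", "BayesA", "BayesB",
                                             "BayesCpi", "BL"),
                      niter = 1500, burnin = 500, thin = 1, seed = 1,
                      pi0 = 0.5, R2 = 0.5, df0 = 5, dfe = 5, fixed = NULL) {
  model <- match.arg(model)
  if (niter <= burnin) stopf("niter must exceed burnin")
  if (!is.list(X_blocks)) X_blocks <- list(X_blocks)
  y <- as.numeric(y)
  if (anyNA(y)) stopf("y must be complete; subset masked rows out first")
  n <- length(y)
  nb <- length(X_blocks)
  X_blocks <- lapply(X_blocks, function(X) {
    X <- as.matrix(X)
    if (nrow(X) != n) stopf("block rows != length(y)")
    X
  })
  centers <- lapply(X_blocks, colMeans)
  Xc <- Map(function(X, ctr) sweep(X, 2L, ctr), X_blocks, centers)
  xx <- lapply(Xc, function(X) colSums(X^2))
  mlen <- vapply(Xc, ncol, integer(1))
  hyp <- gibbs_hyper(y, xx, R2, df0, dfe, n)
  clamp_b <- !is.null(fixed$sigma2_beta)
  clamp_e <- !is.null(fixed$sigma2_e)
  sig2b_fix <- if (clamp_b) rep_len(fixed$sigma2_beta, nb)

  with_seed(seed, {
    mu <- mean(y)
    e <- y - mu
    b <- lapply(mlen, numeric)
    # block-level variances (BRR, BayesCpi) and marker-level (BayesA/B, BL)
    sig2b <- if (clamp_b) as.list(sig2b_fix) else
      lapply(hyp$S0, function(s) s / (df0 + 2))
    sig2m <- Map(function(m, s) rep(s / (df0 + 2), m), mlen, hyp$S0)
    tau2 <- lapply(mlen, function(m) rep(1, m))
    incl <- lapply(mlen, function(m) rep(TRUE, m))
    pi_in <- pi0
    sig2e <- if (clamp_e) fixed$sigma2_e else hyp$vy * (1 - R2)
    keep_it <- rep(FALSE, niter)
    keep_it[seq(burnin + thin, niter, by = thin)] <- TRUE
    n_keep <- sum(keep_it)
    beta_sum <- lapply(mlen, numeric)
    beta_sq <- lapply(mlen, numeric)
    mu_sum <- 0
    chains <- matrix(NA_real_, n_keep, 2L + nb,
                     dimnames = list(NULL, c("sigma2_e", "pi",
                                             paste0("sigma2_block", seq_len(nb)))))
    krow <- 0L
    mixture <- model %in% c("BayesB", "BayesCpi")

    for (it in seq_len(niter)) {
      # intercept
      mu_new <- stats::rnorm(1L, mu + mean(e), sqrt(sig2e / n))
      e <- e - (mu_new - mu)
      mu <- mu_new
      for (kb in seq_len(nb)) {
        Xb <- Xc[[kb]]; xxb <- xx[[kb]]; bb <- b[[kb]]
        vb <- switch(model,
                     BRR = rep(sig2b[[kb]], mlen[kb]),
                     BayesCpi = rep(sig2b[[kb]], mlen[kb]),
                     BayesA = sig2m[[kb]],
                     BayesB = sig2m[[kb]],
                     BL = sig2e * tau2[[kb]])
        inc <- incl[[kb]]
        for (j in seq_len(mlen[kb])) {
          if (xxb[j] <= 0) next
          xj <- Xb[, j]
          bj <- bb[j]
          r <- sum(xj * e) + xxb[j] * bj
          if (mixture) {
            v_spike <- xxb[j] * sig2e
            v_slab <- v_spike + xxb[j]^2 * vb[j]
            lo <- log(pi_in) - log1p(-pi_in) +
              stats::dnorm(r, 0, sqrt(v_slab), log = TRUE) -
              stats::dnorm(r, 0, sqrt(v_spike), log = TRUE)
            inc[j] <- stats::runif(1L) < 1 / (1 + exp(-lo))
          }
          if (!mixture || inc[j]) {
            Cj <- xxb[j] + sig2e / vb[j]
            b_new <- stats::rnorm(1L, r / Cj, sqrt(sig2e / Cj))
          } else {
            b_new <- 0
          }
          if (b_new != bj) {
            e <- e - xj * (b_new - bj)
            bb[j] <- b_new
          }
        }
        b[[kb]] <- bb
        incl[[kb]] <- inc
        # variance updates
        if (!clamp_b) {
          if (model == "BRR") {
            sig2b[[kb]] <- rscaled_inv_chisq(df0 + mlen[kb],
                                             hyp$S0[[kb]] + sum(bb^2))
          } else if (model == "BayesCpi") {
            m_in <- sum(inc)
            sig2b[[kb]] <- rscaled_inv_chisq(df0 + m_in,
                                             hyp$S0[[kb]] + sum(bb[inc]^2))
          } else if (model %in% c("BayesA", "BayesB")) {
            sig2m[[kb]] <- (hyp$S0[[kb]] + bb^2) /
              stats::rchisq(mlen[kb], df = df0 + 1)
          } else if (model == "BL") {
            lam2 <- hyp$lambda2[[kb]]
            nz <- abs(bb) > 1e-12
            t2 <- tau2[[kb]]
            if (any(nz)) {
              t2[nz] <- 1 / rinv_gaussian(sum(nz),
                                          sqrt(lam2 * sig2e / bb[nz]^2), lam2)
            }
            t2[!nz] <- stats::rexp(sum(!nz), rate = lam2 / 2)
            tau2[[kb]] <- pmax(t2, 1e-12)
          }
        }
      }
      if (model == "BayesCpi") {
        m_in <- sum(vapply(incl, sum, numeric(1)))
        m_all <- sum(mlen)
        pi_in <- stats::rbeta(1L, 1 + m_in, 1 + m_all - m_in)
        pi_in <- min(max(pi_in, 1e-6), 1 - 1e-6)
      }
      if (!clamp_e) {
        ss <- hyp$Se + sum(e^2)
        dof <- dfe + n
        if (model == "BL") {
          # sigma2_e also scales the effect prior in the Bayesian LASSO
          for (kb in seq_len(nb)) {
            nz <- abs(b[[kb]]) > 1e-12
            ss <- ss + sum(b[[kb]][nz]^2 / tau2[[kb]][nz])
            dof <- dof + sum(nz)
          }
        }
        sig2e <- rscaled_inv_chisq(dof, ss)
        if (!is.finite(sig2e) || sig2e <= 0) {
          stopf("residual variance chain diverged at iteration %d", it)
        }
      }
      if (keep_it[it]) {
        krow <- krow + 1L
        mu_sum <- mu_sum + mu
        for (kb in seq_len(nb)) {
          beta_sum[[kb]] <- beta_sum[[kb]] + b[[kb]]
          beta_sq[[kb]] <- beta_sq[[kb]] + b[[kb]]^2
        }
        chains[krow, "sigma2_e"] <- sig2e
        chains[krow, "pi"] <- if (model == "BayesCpi") pi_in else pi0
        for (kb in seq_len(nb)) {
          chains[krow, 2L + kb] <- switch(model,
            BRR = sig2b[[kb]], BayesCpi = sig2b[[kb]],
            BayesA = mean(sig2m[[kb]]), BayesB = mean(sig2m[[kb]]),
            BL = mean(sig2e * tau2[[kb]]))
        }
      }
    }
    structure(list(mu = mu_sum / n_keep,
                   beta_mean = lapply(beta_sum, function(s) s / n_keep),
                   beta_sd = Map(function(s, s2) {
                     sqrt(pmax(s2 / n_keep - (s / n_keep)^2, 0))
                   }, beta_sum, beta_sq),
                   centers = centers,
                   chains = as.data.frame(chains),
                   model = model, niter = niter, burnin = burnin,
                   thin = thin, seed = seed),
              class = "gibbs_fit")
  })
}

#' Genomic estimated breeding values from a Gibbs fit
#'
#' `mu + sum_b (X_b - centers_b) beta_b` over any row set whose blocks are
#' column-aligned with the training blocks.
#'
#' @param fit a [gibbs_fit()] result.
#' @param X_blocks list of marker matrices (or one matrix) matching the
#'   training block columns.
#' @return numeric gEBV vector.
#' @export
predict_gebv <- function(fit, X_blocks) {
  if (!is.list(X_blocks)) X_blocks <- list(X_blocks)
  if (length(X_blocks) != length(fit$beta_mean)) {
    stopf("expected %d marker block(s), got %d",
          length(fit$beta_mean), length(X_blocks))
  }
  out <- rep(fit$mu, nrow(as.matrix(X_blocks[[1L]])))
  for (kb in seq_along(X_blocks)) {
    X <- as.matrix(X_blocks[[kb]])
    if (ncol(X) != length(fit$beta_mean[[kb]])) {
      stopf("block %d has %d columns, expected %d",
            kb, ncol(X), length(fit$beta_mean[[kb]]))
    }
    out <- out + as.vector(sweep(X, 2L, fit$centers[[kb]]) %*% fit$beta_mean[[kb]])
  }
  out
}

#' Prediction accuracy as a Pearson correlation
#'
#' Correlation between predicted breeding values and observed phenotypes on
#' the inference rows. With fewer than 3 complete pairs, or zero variance in
#' either vector, the accuracy is undefined and returned as `NA` (callers
#' exclude and count such cases).
#'
#' @param pred,observed numeric vectors of equal length; `NA`s are dropped
#'   pairwise.
#' @return list of class `gs_accuracy`: `r`, `n_used`, `defined`.
#' @export
accuracy <- function(pred, observed) {
  ok <- !is.na(pred) & !is.na(observed)
  n_used <- sum(ok)
  if (n_used < 3L) {
    return(structure(list(r = NA_real_, n_used = n_used, defined = FALSE),
                     class = "gs_accuracy"))
  }
  if (stats::sd(pred[ok]) == 0 || stats::sd(observed[ok]) == 0) {
    return(structure(list(r = NA_real_, n_used = n_used, defined = FALSE),
                     class = "gs_accuracy"))
  }
  structure(list(r = stats::cor(pred[ok], observed[ok]), n_used = n_used,
                 defined = TRUE),
            class = "gs_accuracy")
}
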