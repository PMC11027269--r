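# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the package's computational paths:
# explicit loops and dense solves only.

# block-structure oracle for the expanded genotype: additive block stacks G
# once per environment, interactive block j holds G on env-j rows only
oracle_expand <- function(G, s) {
  n <- nrow(G); m <- ncol(G)
  X <- matrix(0, s * n, s * m)
  for (e in seq_len(s)) {
    rows <- ((e - 1) * n + 1):(e * n)
    X[rows, seq_len(m)] <- G
  }
  for (j in 2:s) {
    rows <- ((j - 1) * n + 1):(j * n)
    cols <- ((j - 1) * m + 1):(j * m)
    X[rows, cols] <- G
  }
  X
}

# dense GLS oracle: explicit inverse of (K + delta I), per-marker fit
oracle_gls <- function(y, x, W, K, sigma2_g, sigma2_e) {
  N <- length(y)
  V0 <- if (sigma2_g > 0) K + (sigma2_e / sigma2_g) * diag(N) else diag(N)
  Vi <- solve(V0)
  X <- cbind(W, x)
  p <- ncol(X)
  M <- t(X) %*% Vi %*% X
  beta <- solve(M, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  sigma2 <- as.numeric(t(res) %*% Vi %*% res) / (N - p)
  covb <- sigma2 * solve(M)
  se <- sqrt(diag(covb))
  tt <- beta / se
  list(beta = as.numeric(beta)[p], se = se[p], t = as.numeric(tt)[p],
       p = 2 * pt(-abs(as.numeric(tt)[p]), N - p))
}

# profiled REML log-likelihood by dense determinants (up to a constant)
oracle_reml_profile <- function(delta, y, W, K) {
  N <- length(y); q <- ncol(W)
  V0 <- K + delta * diag(N)
  Vi <- solve(V0)
  WtVi <- t(W) %*% Vi
  P <- Vi - t(WtVi) %*% solve(WtVi %*% W, WtVi)
  s2 <- as.numeric(t(y) %*% P %*% y) / (N - q)
  -0.5 * ((N - q) * log(s2) + determinant(V0)$modulus +
            determinant(WtVi %*% W)$modulus)
}

# exhaustive recount oracle for power / false-positive-rate curves
oracle_power_fdr <- function(flags, m_r, M_f) {
  tp <- fp <- numeric(length(flags))
  for (t in seq_along(flags)) {
    tp[t] <- sum(flags[seq_len(t)])
    fp[t] <- sum(!flags[seq_len(t)])
  }
  list(power = tp / m_r, fdr = if (M_f > 0) fp / M_f else fp * 0)
}

# Henderson mixed-model-equation oracle for GBLUP on the training rows
oracle_mme <- function(y, K, sigma2_u, sigma2_e) {
  n <- length(y)
  lambda <- sigma2_e / sigma2_u
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + solve(K) * lambda))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(C, rhs)
  list(mu = sol[1L], u = sol[-1L])
}

# ridge-regression oracle on centered markers
oracle_ridge <- function(Z_train, y_train, lambda) {
  m <- ncol(Z_train)
  solve(crossprod(Z_train) + lambda * diag(m), crossprod(Z_train, y_train))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# run code under a local seed without disturbing the suite's RNG stream
with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

tiny_geno <- function(n, m, seed = 1, n_chrom = 2) {
  generate_synthetic_genotypes(n, m, n_chrom = n_chrom, seed = seed)
}

# HapMap text fixture: calls_by_marker is a list of character vectors
write_hapmap_fixture <- function(path, calls_by_marker, chrom, pos,
                                 ids = NULL) {
  n <- length(calls_by_marker[[1L]])
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode", ids)
  lines <- vapply(seq_along(calls_by_marker), function(j) {
    paste(c(paste0("mk", j), "N/N", chrom[j], pos[j], "+", rep("NA", 6),
            calls_by_marker[[j]]), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  path
}
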