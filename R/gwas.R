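#' VanRaden-style genomic relationship matrix
#'
#' Centers each column by its mean and forms `K = Z Z' / c` with
#' `c = sum_j mean(z_j^2)`, so the mean diagonal is exactly 1 on polymorphic
#' data. Zero-variance columns contribute nothing. For the expanded
#' genotype-by-environment matrix this is the "whole kinship" built from the
#' additive and interactive columns together.
#'
#' @param X numeric matrix (individuals or stacked individual-environment
#'   rows x markers), or a `geno_matrix`/`gbye_geno` object.
#' @return list of class `kinship`: `K` (N x N), `scale` (the divisor c),
#'   `source` ("matrix", "geno_matrix" or "gbye_geno").
#' @export
compute_kinship <- function(X) {
  src <- "matrix"
  if (inherits(X, "geno_matrix")) { src <- "geno_matrix"; X <- X$values }
  if (inherits(X, "gbye_geno")) { src <- "gbye_geno"; X <- X$values }
  X <- as.matrix(X)
  Z <- sweep(X, 2L, colMeans(X))
  css <- colSums(Z^2)
  cc <- sum(css) / nrow(X)
  if (cc == 0) stopf("all genotype columns have zero variance; kinship undefined")
  K <- tcrossprod(Z) / cc
  K <- (K + t(K)) / 2
  structure(list(K = K, scale = cc, source = src), class = "kinship")
}

#' Principal-component covariates from a genotype-like matrix
#'
#' First `k` principal-component scores of the column-centered matrix,
#' computed from the eigendecomposition of the centered cross-product. Each
#' component's sign is fixed so that its largest-magnitude score is positive.
#'
#' @param X numeric matrix or `geno_matrix`/`gbye_geno`.
#' @param k number of components (default 3, the usual population-structure
#'   adjustment in maize-panel association scans).
#' @return N x k matrix of scores.
#' @export
compute_pcs <- function(X, k = 3) {
  if (inherits(X, "geno_matrix")) X <- X$values
  if (inherits(X, "gbye_geno")) X <- X$values
  X <- as.matrix(X)
  if (k >= nrow(X)) stopf("k must be smaller than the number of rows")
  Z <- sweep(X, 2L, colMeans(X))
  ee <- eigen(tcrossprod(Z), symmetric = TRUE)
  if (k >= sum(ee$values > 1e-8)) stopf("k=%d is not below the matrix rank", k)
  scores <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ee$values[seq_len(k)], 0)), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# restricted log-likelihood in delta = sigma2_e / sigma2_g after projecting
# the kinship off the fixed effects (EMMA formulation); xi = projected
# eigenvalues, eta = rotated phenotype
reml_loglik <- function(delta, xi, eta2) {
  nq <- length(xi)
  ss <- sum(eta2 / (xi + delta))
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(ss) - sum(log(xi + delta)))
}

#' REML variance components under the null mixed model
#'
#' Fits `y = W b + u + e` with `u ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`
#' by eigendecomposition of the kinship projected off the fixed effects and a
#' one-dimensional REML search over `delta = sigma2_e / sigma2_g`
#' (log-spaced grid on \[1e-5, 1e5\] with golden-section refinement).
#'
#' @param y numeric response, no missing values.
#' @param covariates numeric matrix of covariates (without intercept; an
#'   intercept is added), or `NULL`.
#' @param K kinship matrix or [compute_kinship()] result.
#' @return list of class `var_comp`: `sigma2_g`, `sigma2_e`, `delta`,
#'   `loglik` (restricted), `n`, `q`.
#' @export
fit_null_reml <- function(y, covariates = NULL, K) {
  if (inherits(K, "kinship")) K <- K$K
  y <- as.numeric(y)
  if (anyNA(y)) stopf("y must be complete; drop masked rows first")
  N <- length(y)
  W <- cbind(`(Intercept)` = rep(1, N), covariates)
  q <- ncol(W)
  if (qr(W)$rank < q) stopf("covariates are rank deficient")
  # rotate into an orthonormal complement of the fixed-effect span, then
  # decompose the projected kinship there (keeps kinship null directions
  # cleanly separated from the fixed effects)
  Q <- qr.Q(qr(W), complete = TRUE)[, (q + 1L):N, drop = FALSE]
  M <- crossprod(Q, K %*% Q)
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  xi <- pmax(ee$values, 0)
  eta2 <- as.vector(crossprod(ee$vectors, crossprod(Q, y)))^2
  grid <- exp(seq(log(1e-5), log(1e5), length.out = 61))
  ll <- vapply(grid, reml_loglik, numeric(1), xi = xi, eta2 = eta2)
  if (!any(is.finite(ll))) stopf("REML likelihood not finite anywhere on the delta grid")
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  # optimize over log10(delta) for a well-scaled search
  f <- function(ld) reml_loglik(10^ld, xi = xi, eta2 = eta2)
  opt <- stats::optimize(f, interval = log10(c(lo, hi)), maximum = TRUE, tol = 1e-8)
  delta <- 10^opt$maximum
  if (opt$objective < max(ll)) { delta <- grid[i]; opt$objective <- max(ll) }
  sigma2_g <- sum(eta2 / (xi + delta)) / (N - q)
  structure(list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g,
                 delta = delta, loglik = opt$objective, n = N, q = q),
            class = "var_comp")
}

#' Mixed-linear-model association scan
#'
#' For each marker column `x_j`, fits the generalized least squares model
#' `y = W b + x_j beta + u + e` with `u ~ N(0, sigma2_g K)`. With
#' `p3d = TRUE` (default) the variance ratio is estimated once under the
#' null ([fit_null_reml()]) and reused for every marker; the scan then runs
#' in the eigenbasis of K, where it is a weighted least squares problem
#' solved in closed form for all markers at once. The marker coefficient is
#' tested with a two-sided t statistic `beta / se(beta)` on
#' `N - q - 1` degrees of freedom (q fixed-effect columns including the
#' intercept, plus the marker). Monomorphic markers are skipped with
#' p = 1; markers collinear with the covariates are skipped with a flag.
#'
#' @param y numeric response (complete).
#' @param markers N x m matrix of marker scores, or a `gbye_geno` (its
#'   column index then labels each result with marker id and effect class).
#' @param covariates covariate matrix without intercept, or `NULL`.
#' @param K kinship matrix or [compute_kinship()] result; `NULL` for a
#'   plain fixed-effects (OLS) scan.
#' @param p3d reuse one null REML fit for all markers (default); with
#'   `p3d = FALSE` the variance ratio is re-estimated by REML for every
#'   marker (slow; small problems only).
#' @param vc optional list `(sigma2_g, sigma2_e)` overriding the REML
#'   estimate (e.g. `sigma2_g = 0` reduces the scan to OLS t-tests).
#' @return data.frame of class `mlm_result`: marker_id, effect_class, beta,
#'   se, t, df, p, skipped; attribute `"vc"` holds the variance components.
#' @export
mlm_scan <- function(y, markers, covariates = NULL, K = NULL, p3d = TRUE,
                     vc = NULL) {
  col_index <- NULL
  if (inherits(markers, "gbye_geno")) {
    col_index <- markers$col_index
    markers <- markers$values
  }
  markers <- as.matrix(markers)
  y <- as.numeric(y)
  N <- length(y); m <- ncol(markers)
  if (nrow(markers) != N) stopf("marker rows != length(y)")
  if (inherits(K, "kinship")) K <- K$K
  W <- cbind(`(Intercept)` = rep(1, N), covariates)
  q <- ncol(W)

  if (is.null(vc)) {
    if (is.null(K)) {
      vc <- list(sigma2_g = 0, sigma2_e = 1)
    } else if (p3d) {
      fit <- fit_null_reml(y, covariates, K)
      vc <- list(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e)
    }
  }

  if (!p3d && !is.null(K)) {
    return(mlm_scan_exact(y, markers, W, K, col_index))
  }

  if (is.null(K) || vc$sigma2_g <= 1e-12 * max(vc$sigma2_e, 1e-300)) {
    d <- rep(1, N)
    yt <- y; Wt <- W; Xt <- markers
  } else {
    delta <- vc$sigma2_e / vc$sigma2_g
    ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
    lam <- pmax(ee$values, 1e-8)
    U <- ee$vectors
    d <- 1 / (lam + delta)
    yt <- as.vector(crossprod(U, y))
    Wt <- crossprod(U, W)
    Xt <- crossprod(U, markers)
  }

  # weighted least squares for all markers at once via the Schur complement
  Wd <- Wt * d
  A <- crossprod(Wt, Wd)                   # q x q
  Ainv <- solve(A)
  wy <- crossprod(Wd, yt)                  # q x 1
  yy <- sum(yt^2 * d)
  B <- crossprod(Wd, Xt)                   # q x m
  xx <- colSums(Xt^2 * d)
  xy <- as.vector(crossprod(Xt, yt * d))
  AB <- Ainv %*% B
  schur <- xx - colSums(B * AB)
  num <- xy - as.vector(crossprod(B, Ainv %*% wy))
  c0 <- as.vector(crossprod(wy, Ainv %*% wy))
  rss0 <- yy - c0

  mono <- apply(markers, 2L, function(x) all(x == x[1L]))
  collinear <- !mono & (schur <= 1e-10 * pmax(xx, 1))
  ok <- !mono & !collinear

  beta <- se <- tval <- rep(NA_real_, m)
  p <- rep(1, m)
  df <- N - q - 1L
  beta[ok] <- num[ok] / schur[ok]
  rss <- pmax(rss0 - num[ok]^2 / schur[ok], 0)
  sigma2 <- rss / df
  se[ok] <- sqrt(sigma2 / schur[ok])
  tval[ok] <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tval[ok]), df)
  p[ok] <- pmax(p[ok], .Machine$double.xmin)  # keep p in (0, 1]

  res <- data.frame(
    marker_id = col_index$marker_id %||% (colnames(markers) %||% paste0("m", seq_len(m))),
    effect_class = col_index$effect_class %||% rep("additive", m),
    beta = beta, se = se, t = tval, df = df, p = p,
    skipped = ifelse(mono, "monomorphic", ifelse(collinear, "collinear", "")),
    stringsAsFactors = FALSE)
  attr(res, "vc") <- vc
  class(res) <- c("mlm_result", class(res))
  res
}

# exact (per-marker REML) scan; the marker joins the fixed effects of the
# null fit each time, so cost is one eigendecomposition per marker
mlm_scan_exact <- function(y, markers, W, K, col_index) {
  N <- length(y); m <- ncol(markers); q <- ncol(W)
  beta <- se <- tval <- rep(NA_real_, m)
  p <- rep(1, m); skipped <- character(m)
  for (j in seq_len(m)) {
    x <- markers[, j]
    if (all(x == x[1L])) { skipped[j] <- "monomorphic"; next }
    Xj <- cbind(W, x)
    if (qr(Xj)$rank < ncol(Xj)) { skipped[j] <- "collinear"; next }
    fit <- fit_null_reml(y, Xj[, -1L, drop = FALSE], K)
    one <- mlm_scan(y, matrix(x), covariates = W[, -1L, drop = FALSE], K = K,
                    vc = list(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e))
    beta[j] <- one$beta; se[j] <- one$se; tval[j] <- one$t; p[j] <- one$p
  }
  res <- data.frame(
    marker_id = if (!is.null(col_index)) col_index$marker_id else
      (colnames(markers) %||% paste0("m", seq_len(m))),
    effect_class = if (!is.null(col_index)) col_index$effect_class else "additive",
    beta = beta, se = se, t = tval, df = N - q - 1L, p = p, skipped = skipped,
    stringsAsFactors = FALSE)
  class(res) <- c("mlm_result", class(res))
  res
}

#' Collapse the redundant tests of an expanded-genotype scan
#'
#' A scan over the expanded genotype tests each original marker once per
#' effect class (1 additive + s-1 interactive copies). This reduces the
#' result to one row per original marker: `mode = "min"` keeps the smallest
#' p across copies (recording the winning class); `mode = "bonf-min"`
#' multiplies that minimum by the number of copies, capped at 1.
#'
#' @param results an [mlm_scan()] data.frame.
#' @param mode `"min"` or `"bonf-min"`.
#' @return data.frame with one row per marker_id, ordered as first seen:
#'   marker_id, effect_class (winning copy), beta, se, t, df, p, n_copies.
#' @export
collapse_pvalues <- function(results, mode = c("min", "bonf-min")) {
  mode <- match.arg(mode)
  if (!all(c("marker_id", "p") %in% names(results))) {
    stopf("results must carry marker_id and p columns")
  }
  grp <- factor(results$marker_id, levels = unique(results$marker_id))
  idx <- split(seq_len(nrow(results)), grp)
  rows <- vapply(idx, function(i) i[which.min(results$p[i])], integer(1))
  out <- results[rows, , drop = FALSE]
  n_copies <- lengths(idx)
  if (mode == "bonf-min") out$p <- pmin(out$p * n_copies, 1)
  out$n_copies <- as.integer(n_copies)
  rownames(out) <- NULL
  out
}

#' One-call association scan on the expanded or mean-method phenotype
#'
#' Builds the kinship and principal components from the matrix entering the
#' model (the expanded genotype-by-environment matrix in `"gbye"` mode, the
#' plain genotype in `"mean"` mode), stacks or averages the normalized
#' phenotypes, and runs [mlm_scan()].
#'
#' @param geno a [geno_matrix()].
#' @param pheno a [pheno_table()].
#' @param mode `"gbye"` or `"mean"`.
#' @param n_pcs number of principal-component covariates (default 3).
#' @param collapse `"none"`, `"min"` or `"bonf-min"` post-processing of the
#'   expanded scan (ignored in mean mode).
#' @param ... passed to [mlm_scan()].
#' @return an [mlm_scan()] result (collapsed if requested) with chrom/pos
#'   columns merged in.
#' @export
gwas_scan <- function(geno, pheno, mode = c("gbye", "mean"), n_pcs = 3,
                      collapse = c("none", "min", "bonf-min"), ...) {
  mode <- match.arg(mode)
  collapse <- match.arg(collapse)
  if (mode == "gbye") {
    env <- build_env_design(length(pheno$env_names), env_names = pheno$env_names)
    gb <- expand_genotypes(geno, env)
    y <- normalize_stack_phenotypes(pheno, env)$y
    X <- gb
    Kmat <- compute_kinship(gb)
  } else {
    y <- mean_phenotype(pheno)
    X <- geno$values
    Kmat <- compute_kinship(geno)
  }
  keep <- !is.na(y)
  Xv <- if (inherits(X, "gbye_geno")) X$values else X
  pcs <- if (n_pcs > 0) compute_pcs(Xv[keep, , drop = FALSE], n_pcs) else NULL
  res <- mlm_scan(y[keep],
                  if (inherits(X, "gbye_geno"))
                    structure(list(values = Xv[keep, , drop = FALSE],
                                   col_index = X$col_index), class = "gbye_geno")
                  else Xv[keep, , drop = FALSE],
                  covariates = pcs, K = Kmat$K[keep, keep], ...)
  if (mode == "gbye" && collapse != "none") res <- collapse_pvalues(res, collapse)
  map <- geno$marker_map
  res$chrom <- map$chrom[match(res$marker_id, map$id)]
  res$pos <- map$pos[match(res$marker_id, map$id)]
  res
}
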