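#' Sample QTN positions
#'
#' Draws `nqtn` distinct marker columns uniformly without replacement from the
#' polymorphic markers of a genotype panel.
#'
#' @param geno a [geno_matrix()].
#' @param nqtn number of causal markers.
#' @param seed integer seed.
#' @return sorted integer vector of marker column indices.
#' @export
sample_qtn <- function(geno, nqtn, seed = 1) {
  poly <- which(!geno$monomorphic)
  if (nqtn < 1 || nqtn > length(poly)) {
    stopf("nqtn must be between 1 and the number of polymorphic markers (%d)",
          length(poly))
  }
  with_seed(seed, sort(sample(poly, nqtn)))
}

#' Sample per-environment QTN effect sizes
#'
#' Effects are drawn row-wise (one row per QTN) from a mean-zero multivariate
#' normal with unit variances and compound-symmetric correlation `r` between
#' environments: the single genetic-correlation parameter that ties marker
#' effects across environments. `r = 1` makes all environment columns
#' identical; `r = 0` makes them independent.
#'
#' @param nqtn number of QTNs (rows).
#' @param s number of environments (columns).
#' @param r genetic correlation; must exceed `-1/(s-1)` for a valid
#'   covariance and be at most 1.
#' @param seed integer seed.
#' @return nqtn x s numeric matrix.
#' @export
sample_effects <- function(nqtn, s, r, seed = 1) {
  if (r > 1 || r <= -1 / max(s - 1, 1)) {
    stopf("genetic correlation r=%.3f gives a non-positive-semidefinite covariance for s=%d",
          r, s)
  }
  with_seed(seed, {
    if (r == 1) {
      z <- stats::rnorm(nqtn)
      matrix(z, nqtn, s)
    } else {
      Sigma <- matrix(r, s, s); diag(Sigma) <- 1
      L <- chol(Sigma)
      matrix(stats::rnorm(nqtn * s), nqtn, s) %*% L
    }
  })
}

#' Simulate correlated multi-environment phenotypes
#'
#' Per environment e, the genetic value is `g_e = G[, qtn] %*% effects[, e]`.
#' The residual SD is scaled from the realized sample variance of `g_e` so
#' that the realized variance ratio targets the heritability:
#' `sd_e = sqrt(var(g_e) (1 - h2) / h2)`; residuals are independent normals,
#' drawn independently across environments (no environmental correlation).
#'
#' @param geno a [geno_matrix()].
#' @param qtn_indices marker column indices from [sample_qtn()].
#' @param effects nqtn x s matrix from [sample_effects()].
#' @param h2 target (additive) heritability, in (0, 1).
#' @param seed integer seed for the residual draw.
#' @param env_names optional environment labels.
#' @return object of class `sim_result`: `phenotypes` (a [pheno_table()]),
#'   `genetic_values` (n x s), `realized_h2` (per environment), and `truth`
#'   (list: qtn_indices, qtn_ids, effects, h2, seed).
#' @export
simulate_phenotypes <- function(geno, qtn_indices, effects, h2, seed = 1,
                                env_names = NULL) {
  if (!(h2 > 0 && h2 < 1)) stopf("h2 must be strictly inside (0, 1)")
  effects <- as.matrix(effects)
  if (length(qtn_indices) != nrow(effects)) stopf("qtn/effect row mismatch")
  G <- geno$values
  s <- ncol(effects); n <- nrow(G)
  if (is.null(env_names)) env_names <- paste0("env", seq_len(s))
  g <- G[, qtn_indices, drop = FALSE] %*% effects
  vg <- apply(g, 2L, stats::var)
  if (any(vg == 0)) stopf("zero genetic variance: selected QTNs carry no polymorphism")
  sd_e <- sqrt(vg * (1 - h2) / h2)
  resid <- with_seed(seed,
    matrix(stats::rnorm(n * s), n, s) %*% diag(sd_e, s))
  y <- g + resid
  realized <- vg / apply(y, 2L, stats::var)
  colnames(g) <- env_names
  structure(list(
    phenotypes = pheno_table(y, geno$individual_ids, env_names),
    genetic_values = g,
    realized_h2 = stats::setNames(realized, env_names),
    truth = list(qtn_indices = qtn_indices,
                 qtn_ids = geno$marker_map$id[qtn_indices],
                 effects = effects, h2 = h2, seed = seed)),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d individuals x %d environments, %d QTNs, target h2=%.2f, realized h2=%s\n",
              nrow(x$phenotypes$values), ncol(x$phenotypes$values),
              length(x$truth$qtn_indices), x$truth$h2,
              paste(sprintf("%.3f", x$realized_h2), collapse = "/")))
  invisible(x)
}

#' One-call multi-environment phenotype simulation
#'
#' Convenience wrapper around [sample_qtn()], [sample_effects()] and
#' [simulate_phenotypes()], deriving the three sub-seeds deterministically
#' from one seed.
#'
#' @param geno a [geno_matrix()].
#' @param nqtn number of causal markers (default 20).
#' @param h2 target heritability.
#' @param r genetic correlation between environments.
#' @param s number of environments (default 2).
#' @param seed master seed.
#' @return a `sim_result`, see [simulate_phenotypes()].
#' @export
simulate_multienv <- function(geno, nqtn = 20, h2 = 0.5, r = 0.5, s = 2,
                              seed = 1) {
  qtn <- sample_qtn(geno, nqtn, seed = seed)
  eff <- sample_effects(nqtn, s, r, seed = seed + 1L)
  simulate_phenotypes(geno, qtn, eff, h2, seed = seed + 2L)
}
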