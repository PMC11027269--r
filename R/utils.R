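#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not disturb a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# natural ordering for chromosome labels: numeric labels numerically,
# everything else alphabetically after them (avoids "1,10,2" bugs)
chrom_order <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, as.character(chrom), pos)
}

# draw from a scaled inverse chi-square: S0/chi2_df is the classic
# conjugate update with S0 = prior scale + data sum of squares
rscaled_inv_chisq <- function(df, S0) {
  S0 / stats::rchisq(1L, df = df)
}

# inverse-Gaussian sampler (Michael, Schucany & Haas transformation);
# used by the Bayesian LASSO tau^-2 update
rinv_gaussian <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  out <- ifelse(u <= mu / (mu + x), x, mu^2 / x)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
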