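#' Build the environment design matrix
#'
#' The s x s design matrix has an all-ones first column (additive effect,
#' the average genetic effect across environments) and, for j >= 2, an
#' indicator column that is 1 only in row j (interaction deviation of
#' environment j from the baseline). For two environments this is the
#' lower-triangular matrix \[\[1,0\],\[1,1\]\]. The baseline environment is
#' moved to row 1, so its rows carry no interactive columns — this avoids the
#' linear dependence that a full set of s indicators would create.
#'
#' @param s number of environments (>= 2).
#' @param baseline index (or name, when `env_names` given) of the baseline
#'   environment; default the first.
#' @param env_names optional environment labels, length `s`.
#' @return object of class `env_design` with elements `E` (s x s matrix),
#'   `env_names` (baseline first) and `baseline`.
#' @export
build_env_design <- function(s, baseline = 1L, env_names = NULL) {
  if (s < 2) stopf("need at least 2 environments, got %d", s)
  if (is.null(env_names)) env_names <- paste0("env", seq_len(s))
  if (length(env_names) != s) stopf("env_names must have length s")
  if (is.character(baseline)) baseline <- match(baseline, env_names)
  if (is.na(baseline) || baseline < 1 || baseline > s) stopf("invalid baseline environment")
  env_names <- c(env_names[baseline], env_names[-baseline])
  E <- cbind(1, rbind(0, diag(s - 1L)))
  storage.mode(E) <- "double"
  dimnames(E) <- list(env_names, c("additive", paste0("int_", env_names[-1L])))
  structure(list(E = E, env_names = env_names, baseline = env_names[1L]),
            class = "env_design")
}

#' Expand a genotype matrix into the genotype-by-environment form
#'
#' Computes the Kronecker product of the environment design with the genotype
#' matrix, giving the (s n) x (s m) expanded genotype whose first m columns
#' stack G once per environment (additive block, \[G;G\] for s = 2) and whose
#' remaining (s-1) blocks of m columns hold G on the rows of one non-baseline
#' environment and zeros elsewhere (interactive blocks, \[0;G\]). Rows are
#' environment-major: all individuals of the baseline environment first.
#'
#' @param geno a [geno_matrix()] or plain numeric matrix.
#' @param env an [build_env_design()] result, or an integer number of
#'   environments (design built with the default baseline).
#' @return object of class `gbye_geno` with elements `values`, `row_index`
#'   (data.frame individual_id, env), `col_index` (data.frame marker_id,
#'   effect_class, env), `s`, `n`, `m`, and the originating `marker_map`
#'   when available.
#' @export
expand_genotypes <- function(geno, env) {
  if (is.numeric(env) && length(env) == 1L) env <- build_env_design(env)
  G <- if (inherits(geno, "geno_matrix")) geno$values else as.matrix(geno)
  n <- nrow(G); m <- ncol(G); s <- nrow(env$E)
  marker_ids <- colnames(G) %||% paste0("m", seq_len(m))
  ind_ids <- rownames(G) %||% paste0("i", seq_len(n))
  X <- kronecker(env$E, G)
  effect_class <- c(rep("additive", m),
                    rep(paste0("interactive:", env$env_names[-1L]), each = m))
  col_env <- c(rep(NA_character_, m), rep(env$env_names[-1L], each = m))
  col_index <- data.frame(marker_id = rep(marker_ids, s),
                          effect_class = effect_class,
                          env = col_env, stringsAsFactors = FALSE)
  row_index <- data.frame(individual_id = rep(ind_ids, s),
                          env = rep(env$env_names, each = n),
                          stringsAsFactors = FALSE)
  dimnames(X) <- list(paste(row_index$individual_id, row_index$env, sep = ":"),
                      ifelse(is.na(col_index$env),
                             paste0(col_index$marker_id, ":add"),
                             paste0(col_index$marker_id, ":", col_index$env)))
  structure(list(values = X, row_index = row_index, col_index = col_index,
                 s = s, n = n, m = m, env = env,
                 marker_map = if (inherits(geno, "geno_matrix")) geno$marker_map else NULL),
            class = "gbye_geno")
}

#' @export
print.gbye_geno <- function(x, ...) {
  cat(sprintf("gbye_geno: %d x %d (%d individuals, %d markers, %d environments)\n",
              nrow(x$values), ncol(x$values), x$n, x$m, x$s))
  invisible(x)
}

#' Split an expanded genotype into additive and interactive blocks
#'
#' @param gbye a [expand_genotypes()] result.
#' @return list with `additive` ((s n) x m) and `interactive`
#'   ((s n) x (s-1) m) matrices; their column-wise concatenation reproduces
#'   the full expanded matrix.
#' @export
split_effects <- function(gbye) {
  add <- gbye$col_index$effect_class == "additive"
  list(additive = gbye$values[, add, drop = FALSE],
       interactive = gbye$values[, !add, drop = FALSE])
}

#' Normalize per environment and stack phenotypes into a single vector
#'
#' Each environment column is z-scored (sample SD, denominator n-1) over its
#' non-missing values, then the columns are stacked environment-major in the
#' same row order as [expand_genotypes()]. Missing entries stay `NA`.
#'
#' @param pheno a [pheno_table()].
#' @param env an [build_env_design()] result whose environments match
#'   `pheno$env_names` (order may differ; the baseline is put first).
#' @return object of class `gbye_pheno`: `y` (length s n, `NA` = masked),
#'   `row_index`, `center`/`scale` per environment, `env_names`.
#' @export
normalize_stack_phenotypes <- function(pheno, env) {
  if (!all(env$env_names %in% pheno$env_names)) {
    stopf("environment names of design and phenotype table differ")
  }
  vals <- pheno$values[, env$env_names, drop = FALSE]
  s <- ncol(vals); n <- nrow(vals)
  ctr <- colMeans(vals, na.rm = TRUE)
  scl <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(vals))
  if (any(n_obs < 2L)) {
    stopf("environment '%s' has fewer than 2 observed phenotypes",
          env$env_names[which(n_obs < 2L)[1L]])
  }
  if (any(scl == 0 | !is.finite(scl))) {
    stopf("environment '%s' has zero phenotypic variance",
          env$env_names[which(scl == 0 | !is.finite(scl))[1L]])
  }
  z <- sweep(sweep(vals, 2L, ctr), 2L, scl, "/")
  y <- as.vector(z)
  row_index <- data.frame(individual_id = rep(pheno$individual_ids, s),
                          env = rep(env$env_names, each = n),
                          stringsAsFactors = FALSE)
  names(y) <- paste(row_index$individual_id, row_index$env, sep = ":")
  structure(list(y = y, row_index = row_index, center = ctr, scale = scl,
                 env_names = env$env_names, n = n, s = s),
            class = "gbye_pheno")
}

#' Across-environment mean phenotype (the "Mean value" comparator)
#'
#' Each environment column is z-scored first, then averaged row-wise over
#' non-missing values; this puts the comparator on the same scale as the
#' stacked phenotype. An individual missing in
#' every environment yields `NA`.
#'
#' @param pheno a [pheno_table()].
#' @return named numeric vector of length n.
#' @export
mean_phenotype <- function(pheno) {
  vals <- pheno$values
  scl <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  if (any(scl == 0 | !is.finite(scl))) {
    stopf("environment '%s' has zero phenotypic variance",
          pheno$env_names[which(scl == 0 | !is.finite(scl))[1L]])
  }
  z <- sweep(sweep(vals, 2L, colMeans(vals, na.rm = TRUE)), 2L, scl, "/")
  out <- rowMeans(z, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  names(out) <- pheno$individual_ids
  out
}

#' Write the expanded genotype matrix to a delimited file
#' @param gbye a [expand_genotypes()] result.
#' @param path output file; header encodes (marker, effect class), first
#'   column encodes (individual, environment).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_gbye_genotype <- function(gbye, path, sep = "\t") {
  df <- data.frame(row = rownames(gbye$values), gbye$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the stacked phenotype vector to a delimited file
#' @param gy a [normalize_stack_phenotypes()] result.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_gbye_phenotype <- function(gy, path, sep = "\t") {
  df <- data.frame(individual_id = gy$row_index$individual_id,
                   env = gy$row_index$env, y = unname(gy$y),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
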