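#' Random k-fold assignment at the individual level
#'
#' Folds partition individuals, not stacked individual-environment rows, so
#' every environment copy of one individual shares a fold.
#'
#' @param individual_ids character vector of unique ids.
#' @param k number of folds.
#' @param seed integer seed; deterministic assignment.
#' @return named integer vector of fold labels (1..k) per individual.
#' @export
kfold_split <- function(individual_ids, k = 5, seed = 1) {
  n <- length(individual_ids)
  if (k > n) stopf("k=%d folds exceed n=%d individuals", k, n)
  if (k < 2) stopf("need at least 2 folds")
  with_seed(seed,
    stats::setNames(sample(rep_len(seq_len(k), n)), individual_ids))
}

#' Mask phenotypes of an inference fold under a missing-data scheme
#'
#' \describe{
#'   \item{standard}{all environment rows of the inference individuals are
#'     masked (classical whole-individual CV).}
#'   \item{single_env_missing}{only the `missing_env` rows of inference
#'     individuals are masked; their other environments stay in training, so
#'     the model can borrow the individual's own phenotype from the observed
#'     environment.}
#'   \item{double_env_missing}{every environment row of the inference
#'     individuals is masked; prediction relies on marker effects alone.}
#' }
#' Genotypes are never masked — only phenotype cells.
#'
#' @param gy a [normalize_stack_phenotypes()] result.
#' @param test_ids individual ids of the inference fold.
#' @param scheme one of the three schemes above.
#' @param missing_env environment name blanked in `single_env_missing`
#'   (default the first environment).
#' @return list: `y` (the stacked phenotype with masked cells `NA`),
#'   `masked` (indices of masked cells), `truth` (their pre-masking values).
#' @export
apply_masking <- function(gy, test_ids,
                          scheme = c("standard", "single_env_missing",
                                     "double_env_missing"),
                          missing_env = NULL) {
  scheme <- match.arg(scheme)
  in_test <- gy$row_index$individual_id %in% test_ids
  if (!any(in_test)) stopf("no stacked rows match the inference ids")
  if (scheme == "single_env_missing") {
    missing_env <- missing_env %||% gy$env_names[1L]
    if (!missing_env %in% gy$env_names) stopf("unknown environment '%s'", missing_env)
    masked <- which(in_test & gy$row_index$env == missing_env)
  } else {
    masked <- which(in_test)
  }
  y <- gy$y
  truth <- y[masked]
  y[masked] <- NA_real_
  list(y = y, masked = masked, truth = truth)
}

cv_engine_fit <- function(y_masked, K, blocks, engine, engine_params) {
  if (engine == "gblup") {
    fit <- gblup_fit(y_masked, K,
                     method = engine_params$method %||% "REML")
    predict(fit)
  } else {
    train <- which(!is.na(y_masked))
    fit <- gibbs_fit(y_masked[train],
                     lapply(blocks, function(X) X[train, , drop = FALSE]),
                     model = engine,
                     niter = engine_params$niter %||% 1500,
                     burnin = engine_params$burnin %||% 500,
                     thin = engine_params$thin %||% 1,
                     seed = engine_params$seed %||% 1,
                     pi0 = engine_params$pi0 %||% 0.5,
                     R2 = engine_params$R2 %||% 0.5)
    predict_gebv(fit, blocks)
  }
}

#' Repeated k-fold cross-validation of expanded-encoding vs mean-method GS
#'
#' For each repeat x fold, masks the inference individuals' phenotypes under
#' the chosen scheme, fits the prediction engine on the remaining cells, and
#' scores the Pearson accuracy between predictions and the observed
#' normalized phenotypes of the masked stacked cells — overall and per
#' environment. Both methods are scored against the same masked cells (the
#' mean method's per-individual gEBV is replicated across the individual's
#' masked environment rows), so the comparison shares one target. The same
#' fold assignments are reused across methods, so method comparisons are
#' paired. Kinships and marker blocks are built once per run.
#'
#' @param geno a [geno_matrix()].
#' @param pheno a [pheno_table()] (no missing values; masking is applied
#'   internally).
#' @param scheme masking scheme, see [apply_masking()].
#' @param engine `"gblup"` or a [gibbs_fit()] model name
#'   (`"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesCpi"`, `"BL"`).
#' @param k folds (default 5).
#' @param reps repeats (default 10; raise to 100 for production runs).
#' @param seed master seed; per-repeat fold seeds derive from it.
#' @param methods which methods to run, subset of `c("gbye", "mean")`.
#' @param missing_env see [apply_masking()].
#' @param engine_params list of engine options ([gblup_fit()] `method`;
#'   [gibbs_fit()] `niter`, `burnin`, `pi0`, `R2`, ...).
#' @return data.frame of class `cv_result`: rep, fold, method, env
#'   (`"all"` or an environment name), accuracy, n_test, defined.
#' @export
run_cv <- function(geno, pheno, scheme = "standard", engine = "gblup",
                   k = 5, reps = 10, seed = 1,
                   methods = c("gbye", "mean"), missing_env = NULL,
                   engine_params = list()) {
  methods <- match.arg(methods, c("gbye", "mean"), several.ok = TRUE)
  env <- build_env_design(length(pheno$env_names), env_names = pheno$env_names)
  gb <- expand_genotypes(geno, env)
  gy <- normalize_stack_phenotypes(pheno, env)
  need_gbye <- "gbye" %in% methods
  need_mean <- "mean" %in% methods
  blocks_gbye <- NULL; K_gbye <- NULL
  if (need_gbye) {
    if (engine == "gblup") K_gbye <- compute_kinship(gb)$K
    else blocks_gbye <- split_effects(gb)
  }
  ybar <- NULL; K_mean <- NULL; blocks_mean <- NULL
  if (need_mean) {
    ybar <- mean_phenotype(pheno)
    if (engine == "gblup") K_mean <- compute_kinship(geno)$K
    else blocks_mean <- list(additive = geno$values)
  }
  ids <- geno$individual_ids
  rows <- list()
  for (rp in seq_len(reps)) {
    folds <- kfold_split(ids, k, seed = seed + 7919L * rp)
    for (f in seq_len(k)) {
      test_ids <- ids[folds == f]
      if (need_gbye) {
        msk <- apply_masking(gy, test_ids, scheme, missing_env)
        pred <- tryCatch(
          cv_engine_fit(msk$y, K_gbye, blocks_gbye, engine, engine_params),
          error = function(err) err)
        if (inherits(pred, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            rep = rp, fold = f, method = "gbye", env = "all",
            accuracy = NA_real_, n_test = length(msk$masked), defined = FALSE)
        } else {
          acc <- accuracy(pred[msk$masked], msk$truth)
          rows[[length(rows) + 1L]] <- data.frame(
            rep = rp, fold = f, method = "gbye", env = "all",
            accuracy = acc$r, n_test = acc$n_used, defined = acc$defined)
          env_of <- gy$row_index$env[msk$masked]
          for (ev in unique(env_of)) {
            sel <- env_of == ev
            acc_e <- accuracy(pred[msk$masked][sel], msk$truth[sel])
            rows[[length(rows) + 1L]] <- data.frame(
              rep = rp, fold = f, method = "gbye", env = ev,
              accuracy = acc_e$r, n_test = acc_e$n_used, defined = acc_e$defined)
          }
        }
      }
      if (need_mean) {
        ym <- ybar
        ym[names(ym) %in% test_ids] <- NA_real_
        msk_cells <- apply_masking(gy, test_ids, scheme, missing_env)
        pred <- tryCatch(
          cv_engine_fit(ym, K_mean, blocks_mean, engine, engine_params),
          error = function(err) err)
        if (inherits(pred, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            rep = rp, fold = f, method = "mean", env = "all",
            accuracy = NA_real_, n_test = length(msk_cells$masked),
            defined = FALSE)
        } else {
          # score on the same masked stacked-phenotype cells as the expanded
          # encoding: the per-individual gEBV is replicated across the
          # individual's masked environment rows
          cell_pred <- pred[match(gy$row_index$individual_id[msk_cells$masked],
                                  ids)]
          acc <- accuracy(cell_pred, msk_cells$truth)
          rows[[length(rows) + 1L]] <- data.frame(
            rep = rp, fold = f, method = "mean", env = "all",
            accuracy = acc$r, n_test = acc$n_used, defined = acc$defined)
          env_of <- gy$row_index$env[msk_cells$masked]
          for (ev in unique(env_of)) {
            sel <- env_of == ev
            acc_e <- accuracy(cell_pred[sel], msk_cells$truth[sel])
            rows[[length(rows) + 1L]] <- data.frame(
              rep = rp, fold = f, method = "mean", env = ev,
              accuracy = acc_e$r, n_test = acc_e$n_used,
              defined = acc_e$defined)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cv_result", class(out))
  out
}

#' Summarize and compare cross-validated methods
#'
#' Per method (overall rows only): mean and SD of fold accuracies, the
#' relative change versus the baseline method, and a paired two-sided t-test
#' on per-repeat mean accuracies against the baseline (folds are shared
#' across methods, so the pairing is by repeat).
#'
#' @param cv a [run_cv()] result (or a row-bound combination with a `method`
#'   column).
#' @param baseline method name the others are compared against
#'   (default `"mean"`).
#' @return data.frame: method, mean_accuracy, sd_accuracy, n, rel_change,
#'   p_paired.
#' @export
compare_methods <- function(cv, baseline = "mean") {
  cv <- cv[cv$env == "all" & cv$defined, , drop = FALSE]
  if (!baseline %in% cv$method) stopf("baseline method '%s' absent", baseline)
  methods <- unique(cv$method)
  base_rep <- tapply(cv$accuracy[cv$method == baseline],
                     cv$rep[cv$method == baseline], mean)
  out <- lapply(methods, function(mt) {
    sub <- cv[cv$method == mt, , drop = FALSE]
    rep_means <- tapply(sub$accuracy, sub$rep, mean)
    shared <- intersect(names(rep_means), names(base_rep))
    pval <- if (mt == baseline || length(shared) < 2L) NA_real_ else {
      dd <- rep_means[shared] - base_rep[shared]
      if (stats::sd(dd) == 0) as.numeric(all(dd == 0)) else
        stats::t.test(dd)$p.value
    }
    data.frame(method = mt,
               mean_accuracy = mean(sub$accuracy),
               sd_accuracy = stats::sd(sub$accuracy),
               n = nrow(sub),
               rel_change = mean(sub$accuracy) /
                 mean(cv$accuracy[cv$method == baseline]) - 1,
               p_paired = pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
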