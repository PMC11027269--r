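#' Build the full heritability-by-correlation simulation grid
#'
#' One-stop test-data factory: a synthetic genotype panel plus one simulated
#' multi-environment phenotype set per (h2, r) grid cell — nine scenarios at
#' the default grids — each with its own deterministically derived seed.
#' With `out_dir` the triples (genotype, phenotype, truth) are written as
#' delimited text plus a MANIFEST of seeds; otherwise everything is returned
#' in memory.
#'
#' @param n,m,n_chrom synthetic panel size (defaults 300 x 1000 over 10
#'   chromosomes, a desk-scale stand-in for a few-thousand-marker panel).
#' @param s environments per scenario (default 2).
#' @param nqtn causal markers per scenario (default 20).
#' @param h2_grid,r_grid heritability and genetic-correlation levels
#'   (defaults 0.2/0.5/0.8 each).
#' @param seed master seed; cell seeds derive from it.
#' @param out_dir optional output directory.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return list of class `fixture_grid`: `geno`, `scenarios` (named list of
#'   `sim_result`s), `manifest` (data.frame of cells and seeds).
#' @export
make_grid <- function(n = 300, m = 1000, n_chrom = 10, s = 2, nqtn = 20,
                      h2_grid = c(0.2, 0.5, 0.8), r_grid = c(0.2, 0.5, 0.8),
                      seed = 42, out_dir = NULL, force = FALSE) {
  geno <- generate_synthetic_genotypes(n, m, n_chrom, seed = seed)
  cells <- expand.grid(h2 = h2_grid, r = r_grid, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$h2, cells$r), , drop = FALSE]
  cell_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                           nrow(cells)))
  scenarios <- vector("list", nrow(cells))
  names(scenarios) <- sprintf("h2_%s_r_%s", cells$h2, cells$r)
  for (i in seq_len(nrow(cells))) {
    scenarios[[i]] <- simulate_multienv(geno, nqtn = nqtn, h2 = cells$h2[i],
                                        r = cells$r[i], s = s,
                                        seed = cell_seeds[i])
  }
  manifest <- cbind(cells, scenario = names(scenarios), seed = cell_seeds,
                    stringsAsFactors = FALSE)
  out <- structure(list(geno = geno, scenarios = scenarios,
                        manifest = manifest),
                   class = "fixture_grid")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
      stopf("output directory %s exists and is not empty (use force = TRUE)",
            out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_numeric(geno, file.path(out_dir, "genotype.txt"),
                  file.path(out_dir, "marker_map.txt"))
    for (nm in names(scenarios)) {
      sc <- scenarios[[nm]]
      dd <- file.path(out_dir, nm)
      dir.create(dd, showWarnings = FALSE)
      write_phenotype(sc$phenotypes, file.path(dd, "phenotype.txt"))
      truth <- data.frame(
        qtn_id = sc$truth$qtn_ids,
        chrom = geno$marker_map$chrom[sc$truth$qtn_indices],
        pos = geno$marker_map$pos[sc$truth$qtn_indices],
        sc$truth$effects, check.names = FALSE)
      colnames(truth)[-(1:3)] <- paste0("effect_", sc$phenotypes$env_names)
      utils::write.table(truth, file.path(dd, "truth.txt"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(manifest, file.path(out_dir, "MANIFEST.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
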