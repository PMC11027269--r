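#' Construct a genotype matrix object
#'
#' A `geno_matrix` holds a numeric genotype matrix coded 0/1/2 (major-allele
#' homozygote = 0, heterozygote = 1, minor homozygote = 2) together with its
#' marker map. Markers are sorted by (chromosome, position) with natural
#' numeric ordering of chromosome labels; monomorphic markers are retained but
#' flagged so association scans can skip them without shifting column indices.
#'
#' @param values integer matrix, individuals in rows, markers in columns,
#'   entries in \{0,1,2\}.
#' @param individual_ids character vector of unique individual ids (rows).
#' @param marker_map data.frame with columns `id`, `chrom`, `pos` (base pairs).
#' @param n_imputed count of imputed missing calls, recorded for logging.
#' @return an object of class `geno_matrix` with elements `values`,
#'   `individual_ids`, `marker_map`, `monomorphic` (logical per marker) and
#'   `n_imputed`.
#' @export
geno_matrix <- function(values, individual_ids, marker_map, n_imputed = 0L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    stopf("genotype matrix contains missing values; impute before construction")
  }
  if (!all(values %in% c(0, 1, 2))) {
    stopf("genotype values must be 0, 1 or 2")
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(values)) {
    stopf("individual_ids length (%d) != rows of genotype (%d)",
          length(individual_ids), nrow(values))
  }
  if (anyDuplicated(individual_ids)) stopf("individual ids must be unique")
  marker_map <- as.data.frame(marker_map, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(marker_map))) {
    stopf("marker_map needs columns id, chrom, pos")
  }
  if (nrow(marker_map) != ncol(values)) {
    stopf("marker_map rows (%d) != markers (%d)", nrow(marker_map), ncol(values))
  }
  marker_map$id <- as.character(marker_map$id)
  marker_map$chrom <- as.character(marker_map$chrom)
  marker_map$pos <- as.integer(marker_map$pos)
  ord <- chrom_order(marker_map$chrom, marker_map$pos)
  values <- values[, ord, drop = FALSE]
  marker_map <- marker_map[ord, , drop = FALSE]
  rownames(marker_map) <- NULL
  dimnames(values) <- list(individual_ids, marker_map$id)
  structure(
    list(values = values,
         individual_ids = individual_ids,
         marker_map = marker_map,
         monomorphic = apply(values, 2L, function(x) length(unique(x)) == 1L),
         n_imputed = as.integer(n_imputed)),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%d chromosome(s), %d monomorphic)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$marker_map$chrom)), sum(x$monomorphic)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

# mode (most frequent value) imputation keeps entries in {0,1,2}
impute_mode <- function(x) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  obs <- x[!miss]
  if (length(obs) == 0L) stopf("marker with all calls missing cannot be imputed")
  tab <- table(obs)
  x[miss] <- as.numeric(names(tab)[which.max(tab)])
  x
}

iupac_codes <- c(A = "AA", C = "CC", G = "GG", T = "TT",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

hapmap_missing <- c("NN", "N", "--", "00", "NA", "", "XX")

#' Read a HapMap genotype file
#'
#' Parses tab-delimited HapMap text (11 metadata columns, then one column per
#' individual; calls may be two-letter, e.g. "AT", or single-letter IUPAC
#' codes). Per marker, the major-allele homozygote is coded 0, heterozygote 1,
#' minor homozygote 2; an allele-frequency tie is broken by alphabetical
#' allele order. Markers with more than two alleles are dropped with a
#' warning; missing calls are imputed with the marker mode.
#'
#' @param path path to a HapMap text file.
#' @return a [geno_matrix()].
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) {
    stopf("malformed HapMap header: expected 11 metadata columns plus >=1 individual, got %d columns",
          ncol(raw))
  }
  first <- tolower(names(raw)[1L])
  if (!grepl("^rs", first)) {
    stopf("malformed HapMap header: first column should be the rs# column, got '%s'",
          names(raw)[1L])
  }
  ids <- names(raw)[-(1:11)]
  n <- length(ids)
  m <- nrow(raw)
  vals <- matrix(NA_real_, n, m)
  keep <- rep(TRUE, m)
  n_imputed <- 0L
  for (j in seq_len(m)) {
    calls <- toupper(as.character(raw[j, -(1:11)]))
    single <- nchar(calls) == 1L
    calls[single] <- unname(iupac_codes[calls[single]])
    calls[calls %in% hapmap_missing | is.na(calls)] <- NA_character_
    alleles <- c(substr(calls, 1L, 1L), substr(calls, 2L, 2L))
    alleles <- alleles[!is.na(alleles) & alleles != "N"]
    tab <- sort(table(alleles), decreasing = TRUE)
    if (length(tab) > 2L) {
      warnf("marker %s has >2 alleles; dropped", raw[j, 1L])
      keep[j] <- FALSE
      next
    }
    if (length(tab) == 0L) {
      warnf("marker %s has no callable genotypes; dropped", raw[j, 1L])
      keep[j] <- FALSE
      next
    }
    # major allele: highest count, ties broken alphabetically
    counts <- as.vector(tab)
    alle <- names(tab)
    major <- alle[order(-counts, alle)][1L]
    minor_count <- vapply(calls, function(cc) {
      if (is.na(cc)) return(NA_real_)
      sum(c(substr(cc, 1L, 1L), substr(cc, 2L, 2L)) != major)
    }, numeric(1))
    n_imputed <- n_imputed + sum(is.na(minor_count))
    vals[, j] <- impute_mode(unname(minor_count))
  }
  map <- data.frame(id = as.character(raw[[1L]]),
                    chrom = as.character(raw[[3L]]),
                    pos = as.integer(raw[[4L]]),
                    stringsAsFactors = FALSE)
  geno_matrix(vals[, keep, drop = FALSE], ids, map[keep, , drop = FALSE],
              n_imputed = n_imputed)
}

#' Read a numeric (0/1/2) genotype matrix
#'
#' @param path delimited file; first column individual or marker ids, header
#'   row carries the other dimension's ids.
#' @param map_path optional 3-column (id, chrom, pos) marker map file; if
#'   omitted, markers are placed on one chromosome at consecutive positions.
#' @param orientation `"individuals-rows"` (default) or `"markers-rows"`.
#' @param missing_code string coding missing entries (imputed by marker mode).
#' @param sep field separator, default tab.
#' @return a [geno_matrix()].
#' @export
read_numeric <- function(path, map_path = NULL,
                         orientation = c("individuals-rows", "markers-rows"),
                         missing_code = "NA", sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = 1L, colClasses = "character",
                           na.strings = missing_code)
  x <- as.matrix(raw)
  suppressWarnings(storage.mode(x) <- "double")
  if (orientation == "markers-rows") x <- t(x)
  bad <- !is.na(x) & !(x %in% c(0, 1, 2))
  if (any(bad)) {
    stopf("numeric genotype contains %d value(s) outside {0,1,2} that are not the missing code",
          sum(bad))
  }
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0L) x <- apply(x, 2L, impute_mode)
  if (!is.null(map_path)) {
    map <- utils::read.table(map_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    names(map)[1:3] <- c("id", "chrom", "pos")
    map <- map[match(colnames(x), map$id), , drop = FALSE]
    if (anyNA(map$id)) stopf("marker map is missing ids present in the genotype file")
  } else {
    map <- data.frame(id = colnames(x), chrom = "1", pos = seq_len(ncol(x)),
                      stringsAsFactors = FALSE)
  }
  geno_matrix(x, rownames(x), map, n_imputed = n_imputed)
}

#' Write a genotype matrix (numeric coding plus marker map)
#'
#' @param geno a [geno_matrix()].
#' @param path output file for the numeric matrix (individuals in rows).
#' @param map_path optional output file for the marker map.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_numeric <- function(geno, path, map_path = NULL, sep = "\t") {
  df <- data.frame(taxa = geno$individual_ids,
                   geno$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    utils::write.table(geno$marker_map, map_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct a phenotype table
#'
#' @param values numeric matrix, individuals in rows, one column per
#'   environment (or trait); `NA` marks a missing/masked phenotype.
#' @param individual_ids character vector aligned to rows.
#' @param env_names character vector aligned to columns.
#' @return an object of class `pheno_table`.
#' @export
pheno_table <- function(values, individual_ids, env_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(env_names)) env_names <- paste0("env", seq_len(ncol(values)))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(values)) stopf("id/row mismatch in phenotype table")
  dimnames(values) <- list(individual_ids, env_names)
  structure(list(values = values,
                 individual_ids = individual_ids,
                 env_names = as.character(env_names)),
            class = "pheno_table")
}

#' @export
print.pheno_table <- function(x, ...) {
  cat(sprintf("pheno_table: %d individuals x %d environment(s) [%s], %d missing\n",
              nrow(x$values), ncol(x$values),
              paste(x$env_names, collapse = ", "), sum(is.na(x$values))))
  invisible(x)
}

#' Read a phenotype table and align it to a genotype matrix
#'
#' First column is the individual id, remaining columns are environments.
#' When `geno` is supplied the rows are reordered to the genotype id order;
#' phenotype-only ids are dropped with a warning.
#'
#' @param path delimited file with a header row.
#' @param geno optional [geno_matrix()] to align against.
#' @param sep field separator.
#' @return a [pheno_table()].
#' @export
read_phenotype <- function(path, geno = NULL, sep = "\t") {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (!is.null(geno)) {
    keep <- ids %in% geno$individual_ids
    if (!any(keep)) stopf("no phenotype ids overlap the genotype ids")
    if (any(!keep)) {
      warnf("%d phenotype id(s) absent from genotype; dropped", sum(!keep))
    }
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
    idx <- match(geno$individual_ids, ids)
    idx <- idx[!is.na(idx)]
    vals <- vals[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  pheno_table(vals, ids, colnames(vals))
}

#' Write a phenotype table
#' @param pheno a [pheno_table()].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path, sep = "\t") {
  df <- data.frame(taxa = pheno$individual_ids, pheno$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic genotype panel
#'
#' Markers are independent: each draws an allele frequency p from
#' Uniform(maf_low, maf_high) and genotypes from Binomial(2, p) — a
#' linkage-free stand-in for a diversity panel, adequate for testing encoding,
#' association and prediction machinery. Markers are assigned evenly to
#' `n_chrom` chromosomes at 1-kb spacing.
#'
#' @param n individuals (>= 2).
#' @param m markers (>= 2).
#' @param n_chrom chromosomes to spread markers over.
#' @param maf_low,maf_high bounds of the allele-frequency draw, in (0, 0.5].
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [geno_matrix()].
#' @export
generate_synthetic_genotypes <- function(n, m, n_chrom = 10, maf_low = 0.05,
                                         maf_high = 0.5, seed = 1) {
  if (n < 2 || m < 2) stopf("need n >= 2 and m >= 2")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stopf("need 0 < maf_low <= maf_high <= 0.5")
  }
  with_seed(seed, {
    p <- stats::runif(m, maf_low, maf_high)
    vals <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    chrom <- rep(seq_len(n_chrom), length.out = m)
    chrom <- sort(chrom)
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
    map <- data.frame(id = sprintf("snp%04d", seq_len(m)),
                      chrom = as.character(chrom), pos = pos,
                      stringsAsFactors = FALSE)
    geno_matrix(vals, sprintf("ind%04d", seq_len(n)), map)
  })
}
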