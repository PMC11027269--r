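#' Flag ranked markers as true QTNs, deduplicating expanded-genotype copies
#'
#' Takes scan results ranked by ascending p-value and returns one row per
#' original marker (the first — best — occurrence of each marker id is kept;
#' later copies are neither true nor false positives), flagged TRUE when the
#' marker is a simulated QTN or, with `window_bp > 0`, lies within that
#' distance of one on the same chromosome. With a window, each QTN is
#' creditable once: a second marker hitting an already-credited QTN is
#' dropped from the list.
#'
#' @param ranked data.frame with `marker_id` and, for windowed matching,
#'   `chrom` and `pos`, sorted by ascending p (ties already broken).
#' @param truth the `truth` element of a `sim_result` (needs `qtn_ids`), or a
#'   character vector of QTN marker ids.
#' @param marker_map marker map (id, chrom, pos); required when
#'   `window_bp > 0` and `ranked` lacks positions.
#' @param window_bp matching window in base pairs (default 0 = identity).
#' @return the deduplicated `ranked` data.frame with a logical `is_true`
#'   column; attribute `"m_r"` is the number of true QTNs.
#' @export
match_qtn <- function(ranked, truth, marker_map = NULL, window_bp = 0) {
  qtn_ids <- if (is.list(truth)) truth$qtn_ids else as.character(truth)
  keep <- !duplicated(ranked$marker_id)
  out <- ranked[keep, , drop = FALSE]
  if (window_bp <= 0) {
    out$is_true <- out$marker_id %in% qtn_ids
  } else {
    if (is.null(marker_map)) {
      if (!all(c("chrom", "pos") %in% names(out))) {
        stopf("windowed matching needs chrom/pos or a marker_map")
      }
      marker_map <- out[, c("marker_id", "chrom", "pos")]
      names(marker_map)[1L] <- "id"
    }
    qmap <- marker_map[marker_map$id %in% qtn_ids, , drop = FALSE]
    if (nrow(qmap) == 0L) stopf("none of the QTN ids are present in the marker map")
    mi <- match(out$marker_id, marker_map$id)
    if (anyNA(mi)) stopf("ranked marker id absent from the marker map")
    chrom <- marker_map$chrom[mi]; pos <- marker_map$pos[mi]
    claimed <- rep(FALSE, nrow(qmap))
    is_true <- rep(FALSE, nrow(out))
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out))) {
      hits <- which(qmap$chrom == chrom[i] & abs(qmap$pos - pos[i]) <= window_bp)
      if (length(hits) == 0L) next
      open <- hits[!claimed[hits]]
      if (length(open) > 0L) {
        claimed[open[1L]] <- TRUE
        is_true[i] <- TRUE
      } else {
        drop[i] <- TRUE
      }
    }
    out$is_true <- is_true
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "m_r") <- length(qtn_ids)
  out
}

#' Power and false-positive-rate curve over a ranked marker list
#'
#' At each rank cut t, power is the fraction of all true QTNs among the top
#' t markers and "FDR" is the fraction of all non-QTN markers declared — as
#' the source formulas print it, a false-positive *rate* over the m - m_r
#' non-QTNs, not the usual false-discovery proportion. Both reach 1 when the
#' full list is declared. The conventional false-discovery proportion
#' (false positives / declarations) is also returned as `fdp`.
#'
#' @param flags logical vector (TRUE = true QTN) in rank order, e.g. the
#'   `is_true` column of [match_qtn()]; or a data.frame carrying `is_true`.
#' @param m_r number of true QTNs (default: number of TRUE flags, correct
#'   whenever the full marker list is ranked).
#' @param M_f number of non-QTN markers (default: number of FALSE flags).
#' @return data.frame of class `power_fdr`: rank, power, fdr, fdp, with
#'   attributes `m_r` and `M_f`.
#' @export
power_fdr_curve <- function(flags, m_r = NULL, M_f = NULL) {
  if (is.data.frame(flags)) flags <- flags$is_true
  flags <- as.logical(flags)
  if (anyNA(flags)) stopf("flags contain NA")
  m_r <- m_r %||% sum(flags)
  M_f <- M_f %||% sum(!flags)
  if (m_r <= 0) stopf("no true QTNs in the ranked list")
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  out <- data.frame(rank = seq_along(flags),
                    power = tp / m_r,
                    fdr = if (M_f > 0) fp / M_f else rep(0, length(flags)),
                    fdp = fp / seq_along(flags))
  attr(out, "m_r") <- m_r
  attr(out, "M_f") <- M_f
  class(out) <- c("power_fdr", class(out))
  out
}

#' Pointwise average of replicate power/FDR curves
#'
#' @param curves list of [power_fdr_curve()] results sharing the same design
#'   (equal length, m_r and M_f).
#' @return data.frame: rank, power, fdr (means), power_sd, fdr_sd.
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0L) stopf("no curves to average")
  len <- vapply(curves, nrow, integer(1))
  mr <- vapply(curves, function(cv) attr(cv, "m_r"), numeric(1))
  mf <- vapply(curves, function(cv) attr(cv, "M_f"), numeric(1))
  if (length(unique(len)) != 1L || length(unique(mr)) != 1L ||
      length(unique(mf)) != 1L) {
    stopf("curves come from heterogeneous designs (length/m_r/M_f differ)")
  }
  P <- vapply(curves, function(cv) cv$power, numeric(len[1L]))
  FD <- vapply(curves, function(cv) cv$fdr, numeric(len[1L]))
  P <- matrix(P, nrow = len[1L]); FD <- matrix(FD, nrow = len[1L])
  out <- data.frame(rank = curves[[1L]]$rank,
                    power = rowMeans(P),
                    fdr = rowMeans(FD),
                    power_sd = apply(P, 1L, stats::sd),
                    fdr_sd = apply(FD, 1L, stats::sd))
  attr(out, "m_r") <- mr[1L]; attr(out, "M_f") <- mf[1L]
  class(out) <- c("power_fdr", class(out))
  out
}

#' Power achieved at a false-positive-rate budget
#'
#' Maximum power among curve points with fdr at most `fdr_level`
#' (step-function reading of the curve); 0 when no point qualifies.
#'
#' @param curve a [power_fdr_curve()] or [average_curves()] result.
#' @param fdr_level budget in \[0, 1\].
#' @return scalar power.
#' @export
power_at_fdr <- function(curve, fdr_level) {
  if (fdr_level < 0 || fdr_level > 1) stopf("fdr_level must be in [0, 1]")
  ok <- curve$fdr <= fdr_level
  if (!any(ok)) return(0)
  max(curve$power[ok])
}

#' Rank scan results for curve evaluation
#'
#' Sorts by ascending p with deterministic tie-breaking on (p, chrom, pos,
#' marker_id).
#'
#' @param results an [mlm_scan()] or [collapse_pvalues()] data.frame.
#' @return the sorted data.frame.
#' @export
rank_results <- function(results) {
  chrom <- results$chrom %||% rep("", nrow(results))
  pos <- results$pos %||% rep(0L, nrow(results))
  num <- suppressWarnings(as.numeric(chrom))
  out <- results[order(results$p, is.na(num), num, as.character(chrom), pos,
                       results$marker_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
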