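#' Plate-level Z-factor
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Z' is at most
#' 1 (a perfect, noiseless assay) and is invariant to affine rescaling
#' of the signal; 0.5 is the conventional bar for a good plate.
#'
#' @param stats a [control_stats()].
#' @return dimensionless Z'.
#' @export
zprime <- function(stats) {
  window <- abs(stats$neg$mean - stats$pos$mean)
  if (window == 0) stop("degenerate controls: zero window")
  1 - 3 * (stats$pos$sd + stats$neg$sd) / window
}

#' Robust strictly standardized mean difference
#'
#' `SSMD = (median_neg - median_pos) / sqrt(MAD_neg^2 + MAD_pos^2)` with
#' 1.4826-scaled MADs, the outlier-resistant version of the control
#' separation. Oriented so a healthy signal-decreasing (viability) assay
#' gives a positive value.
#'
#' @param stats a [control_stats()].
#' @return dimensionless SSMD.
#' @export
ssmd_robust <- function(stats) {
  s <- sqrt(stats$neg$mad^2 + stats$pos$mad^2)
  if (s == 0) stop("degenerate controls: both MADs zero")
  (stats$neg$median - stats$pos$median) / s
}

#' Sample-based plate QC using block DMSO wells
#'
#' Recomputes Z' and SSMD replacing the plate negative controls by the
#' per-block DMSO corner wells (positive controls unchanged). Because
#' the block controls are scattered through the sample field, these
#' variants feel plate-wide artifacts (drift, edge effects) that
#' one-sided control columns miss. They are considered meaningful only
#' on plates holding at least 12 blocks; below that the result is
#' returned flagged, not refused.
#'
#' @param plate a normalized `mqc_plate`.
#' @param blocks optional block list from [deconvolute_blocks()];
#'   deconvoluted on the fly when missing.
#' @return list: `zprime_sample`, `ssmd_sample`, `n_blocks`,
#'   `meaningful` (logical flag).
#' @export
sample_plate_qc <- function(plate, blocks = NULL) {
  if (is.null(blocks)) blocks <- deconvolute_blocks(plate)
  dmso <- vapply(blocks, function(b) b$responses[b$n, b$n], 0)
  pos <- plate$wells$signal[plate$wells$role == "pos"]
  st <- control_stats(neg = dmso, pos = pos)
  list(zprime_sample = zprime(st),
       ssmd_sample = ssmd_robust(st),
       n_blocks = length(blocks),
       meaningful = length(blocks) >= 12)
}

#' Per-plate QC table
#'
#' Convenience wrapper producing the CSV-ready table of plate and
#' sample-based statistics for a list of plates.
#'
#' @param plates list of raw `mqc_plate` (normalized internally for the
#'   sample variants).
#' @return data.frame `plate_id, zprime, ssmd, zprime_sample,
#'   ssmd_sample, sample_flag, n_blocks`.
#' @export
plate_qc_table <- function(plates) {
  if (inherits(plates, "mqc_plate")) plates <- list(plates)
  do.call(rbind, lapply(plates, function(p) {
    st <- control_stats(plate = p)
    norm <- normalize_plate(p, st)
    sq <- tryCatch(sample_plate_qc(norm), error = function(e)
      list(zprime_sample = NA_real_, ssmd_sample = NA_real_,
           n_blocks = 0L, meaningful = FALSE))
    data.frame(plate_id = p$plate_id, zprime = zprime(st),
               ssmd = ssmd_robust(st), zprime_sample = sq$zprime_sample,
               ssmd_sample = sq$ssmd_sample,
               sample_flag = !sq$meaningful, n_blocks = sq$n_blocks)
  }))
}
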