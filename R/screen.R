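#' Aggregate block predictions into a screen report
#'
#' Applies the confidence filter (predictions with calibrated confidence
#' below `confidence_min` are removed, mirroring production practice of
#' dropping low-confidence grades before screen statistics) and computes
#' the percentage of Good and of Good-or-Medium blocks, together with a
#' Z' summary over the screen's plates.
#'
#' @param predictions an `mqc_prediction` data.frame (or any data.frame
#'   with `label` and `confidence` columns).
#' @param zprime_values per-plate Z' values for the screen.
#' @param confidence_min filter threshold (default 0.6).
#' @param screen_id identifier.
#' @return list of class `screen_report`: `pct_good`,
#'   `pct_good_or_medium`, `zprime_mean`, `zprime_sd`, `n_total`,
#'   `n_filtered`, `confidence_min`.
#' @export
aggregate_screen <- function(predictions, zprime_values,
                             confidence_min = 0.6, screen_id = "screen") {
  keep <- !is.na(predictions$confidence) &
    predictions$confidence >= confidence_min
  n_total <- nrow(predictions)
  kept <- predictions[keep, ]
  if (!nrow(kept)) stop("no confident predictions survive the filter")
  structure(list(
    screen_id = screen_id,
    pct_good = 100 * mean(kept$label == "Good"),
    pct_good_or_medium = 100 * mean(kept$label %in% c("Good", "Medium")),
    zprime_mean = mean(zprime_values),
    zprime_sd = stats::sd(zprime_values),
    n_total = n_total,
    n_filtered = n_total - nrow(kept),
    confidence_min = confidence_min),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s: Z' %.2f +/- %.2f; %.1f%% Good, %.1f%% Good+Medium (%d/%d blocks filtered)\n",
              x$screen_id, x$zprime_mean, x$zprime_sd, x$pct_good,
              x$pct_good_or_medium, x$n_filtered, x$n_total))
  invisible(x)
}

#' Combined plate + matrix QC guideline verdict
#'
#' A combination screen passes when all three strict criteria hold:
#' (1) mean Z' > 0.5, (2) more than 60% Good blocks, (3) more than 90%
#' Good-or-Medium blocks. Failures are labeled `plate-level fail` (Z'
#' criterion), `matrix-level fail` (either block criterion) or both;
#' each direction points at a different failure family (failed controls
#' or biased layout vs. cell, readout or handling problems affecting
#' the sample field).
#'
#' @param report a `screen_report` (or a list with `zprime_mean`,
#'   `pct_good`, `pct_good_or_medium`).
#' @param zprime_min,good_min,good_medium_min guideline thresholds.
#' @return list: `pass`, per-criterion logical flags, `verdict` string.
#' @export
guideline_verdict <- function(report, zprime_min = 0.5, good_min = 60,
                              good_medium_min = 90) {
  crit <- c(zprime = report$zprime_mean > zprime_min,
            good = report$pct_good > good_min,
            good_or_medium = report$pct_good_or_medium > good_medium_min)
  plate_fail <- !crit["zprime"]
  matrix_fail <- !crit["good"] || !crit["good_or_medium"]
  verdict <- if (!plate_fail && !matrix_fail) "pass"
    else if (plate_fail && matrix_fail) "plate-level and matrix-level fail"
    else if (plate_fail) "plate-level fail"
    else "matrix-level fail"
  list(pass = all(crit), criteria = crit, verdict = verdict)
}

#' Exact trinomial paired-comparison test
#'
#' For m matched block pairs graded on the ordinal QC scale, let
#' `n_plus`, `n_zero`, `n_minus` count the pairs where side 1 is better,
#' equal or worse. Under the null that gradings are exchangeable each
#' pair lands in the three outcomes with probability 1/3, and the
#' p-value is the exact tail probability
#' `P(X_plus - X_minus >= n_plus - n_minus)` under
#' Multinomial(m; 1/3, 1/3, 1/3), computed by dynamic-programming
#' convolution of m i.i.d. steps in {+1, 0, -1}. Beyond `max_exact`
#' pairs a normal approximation with continuity correction is used.
#'
#' @param n_plus,n_zero,n_minus outcome counts.
#' @param max_exact largest m solved exactly (default 5000).
#' @return p-value in (0, 1].
#' @export
trinomial_test <- function(n_plus, n_zero, n_minus, max_exact = 5000) {
  m <- n_plus + n_zero + n_minus
  if (m == 0) stop("no matched pairs")
  d_obs <- n_plus - n_minus
  if (m > max_exact) {
    # D = X+ - X-: mean 0, var 2m/3
    z <- (d_obs - 0.5) / sqrt(2 * m / 3)
    return(stats::pnorm(z, lower.tail = FALSE))
  }
  # dist[k] = P(D = k - m - 1), support -m..m
  dist <- numeric(2 * m + 1)
  dist[m + 1] <- 1
  third <- 1 / 3
  for (s in seq_len(m)) {
    up <- c(dist[-1], 0)       # shift towards -1... see below
    down <- c(0, dist[-(2 * m + 1)])
    dist <- third * (up + dist + down)
  }
  # 'down' shifts mass to larger D, 'up' to smaller D; symmetric so either way
  sum(dist[(m + 1 + d_obs):(2 * m + 1)])
}

#' Paired ordinal comparison of two block populations
#'
#' Matches blocks across two prediction tables on the supplied key
#' columns (all experimental settings except the compared factor, e.g.
#' cell line + compound pair when comparing readouts), grades each pair
#' on the ordinal scale Good > Medium > Bad, and tests whether side A
#' is better than side B with the exact trinomial test. Predictions
#' below the confidence filter are excluded before matching.
#'
#' @param a,b data.frames with `label`, the key columns, and optionally
#'   `confidence`.
#' @param keys character vector of matching column names.
#' @param confidence_min confidence filter (default 0.6; set to 0 to
#'   disable).
#' @return list of class `paired_comparison`: `m`, `n_plus`, `n_zero`,
#'   `n_minus`, `p_value`.
#' @export
paired_compare <- function(a, b, keys, confidence_min = 0.6) {
  filt <- function(d) {
    if (!is.null(d$confidence))
      d <- d[!is.na(d$confidence) & d$confidence >= confidence_min, ]
    d
  }
  a <- filt(a); b <- filt(b)
  m <- merge(a[c(keys, "label")], b[c(keys, "label")], by = keys,
             suffixes = c(".a", ".b"))
  if (!nrow(m)) stop("no matched pairs on the given keys")
  ord <- c(Bad = 1, Medium = 2, Good = 3)
  da <- ord[m$label.a]; db <- ord[m$label.b]
  n_plus <- sum(da > db); n_minus <- sum(da < db)
  n_zero <- sum(da == db)
  structure(list(m = nrow(m), n_plus = n_plus, n_zero = n_zero,
                 n_minus = n_minus,
                 p_value = trinomial_test(n_plus, n_zero, n_minus)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> m=%d: better %d, equal %d, worse %d; p = %.3g\n",
              x$m, x$n_plus, x$n_zero, x$n_minus, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (wrapper over [stats::p.adjust()]); comparisons with adjusted
#' p < 0.05 are conventionally reported as significant.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}
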