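#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's K-category generalization of the MCC computed from a
#' K x K confusion matrix with entries `C[i, j]` = cases of true class i
#' predicted as class j. Equals the familiar binary MCC when K = 2;
#' returns 0 by convention when the denominator vanishes (e.g. a
#' single-class prediction).
#'
#' @param confusion K x K count matrix (true classes in rows).
#' @return MCC in `[-1, 1]`.
#' @export
multiclass_mcc <- function(confusion) {
  C <- as.matrix(confusion)
  s <- sum(C)
  if (s <= 0) stop("empty confusion matrix")
  c_ <- sum(diag(C))
  t_ <- rowSums(C)    # true-class totals
  p_ <- colSums(C)    # predicted-class totals
  num <- c_ * s - sum(p_ * t_)
  den <- sqrt(s^2 - sum(p_^2)) * sqrt(s^2 - sum(t_^2))
  if (den == 0) return(0)
  num / den
}

#' Per-class recall and precision
#'
#' `recall_i = C[i,i] / sum_j C[i,j]`, `precision_i = C[i,i] / sum_j C[j,i]`.
#' A 0/0 ratio (empty true or predicted class) is reported as NA.
#'
#' @param confusion K x K count matrix (true classes in rows).
#' @param class row/column name or index.
#' @return named numeric `c(recall, precision)`.
#' @export
class_recall_precision <- function(confusion, class) {
  C <- as.matrix(confusion)
  i <- if (is.character(class)) match(class, rownames(C)) else class
  if (is.na(i) || i < 1 || i > nrow(C)) stop("unknown class")
  rec <- if (sum(C[i, ]) == 0) NA_real_ else C[i, i] / sum(C[i, ])
  pre <- if (sum(C[, i]) == 0) NA_real_ else C[i, i] / sum(C[, i])
  c(recall = rec, precision = pre)
}

#' Repeated-split validation of the QC classifier
#'
#' Runs the train/test validation protocol: for each test-set proportion
#' (default 5% to 80% in 5% steps) draw `n_splits` stratified random
#' splits, train the boosted-tree model on the training part and score
#' the held-out part. A split whose training part lost a class entirely
#' is redrawn (counted in `n_resampled`). Reports the multiclass MCC per
#' split and pooled confusion matrices per proportion.
#'
#' @param x feature data.frame (see [mqc()]).
#' @param y class labels.
#' @param proportions test-set proportions.
#' @param n_splits random splits per proportion (default 200).
#' @param seed RNG seed for the split sequence.
#' @param ... hyperparameters forwarded to [mqc()] (calibration is off
#'   during validation).
#' @return object of class `mqc_validation`: `results` data.frame
#'   (proportion, split, mcc, recall/precision per class), `pooled`
#'   confusion per proportion, `n_resampled`.
#' @export
mqc_validate <- function(x, y, proportions = seq(0.05, 0.80, by = 0.05),
                         n_splits = 200, seed = 1, ...) {
  y <- canonical_labels(y)
  X <- as.matrix(x[MQC_FEATURES])
  K <- nlevels(y)
  classes <- levels(y)
  set.seed(seed)
  rows <- vector("list", length(proportions) * n_splits)
  pooled <- stats::setNames(
    rep(list(matrix(0, K, K, dimnames = list(classes, classes))),
        length(proportions)),
    as.character(proportions))
  n_resampled <- 0L
  r <- 0L
  for (pi in seq_along(proportions)) {
    p <- proportions[pi]
    for (s in seq_len(n_splits)) {
      repeat {
        test_idx <- stratified_test_idx(y, p)
        if (length(unique(y[-test_idx])) == K) break
        n_resampled <- n_resampled + 1L
      }
      fit <- mqc(as.data.frame(X[-test_idx, , drop = FALSE]),
                 y[-test_idx], calibrate = FALSE, ...)
      pred <- predict(fit, as.data.frame(X[test_idx, , drop = FALSE]))
      cm <- table(factor(as.character(y[test_idx]), levels = classes),
                  factor(pred$label, levels = classes))
      pooled[[pi]] <- pooled[[pi]] + unclass(cm)
      rp <- lapply(classes, function(k) class_recall_precision(cm, k))
      row <- data.frame(proportion = p, split = s,
                        mcc = multiclass_mcc(cm))
      for (ki in seq_along(classes)) {
        row[[paste0("recall_", classes[ki])]] <- rp[[ki]]["recall"]
        row[[paste0("precision_", classes[ki])]] <- rp[[ki]]["precision"]
      }
      r <- r + 1L
      rows[[r]] <- row
    }
  }
  structure(list(results = do.call(rbind, rows), pooled = pooled,
                 proportions = proportions, n_splits = n_splits,
                 classes = classes, n_resampled = n_resampled),
            class = "mqc_validation")
}

stratified_test_idx <- function(y, p) {
  idx <- integer(0)
  for (k in levels(y)) {
    ik <- which(y == k)
    nk <- max(1L, min(length(ik) - 1L, round(p * length(ik))))
    idx <- c(idx, sample(ik, nk))
  }
  idx
}

#' @export
print.mqc_validation <- function(x, ...) {
  agg <- stats::aggregate(mcc ~ proportion, data = x$results, FUN = mean)
  cat(sprintf("<mqc_validation> %d proportions x %d splits (%d resampled)\n",
              length(x$proportions), x$n_splits, x$n_resampled))
  cat("  mean multiclass MCC by test proportion:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %4.0f%%  %.3f\n", 100 * agg$proportion[i], agg$mcc[i]))
  invisible(x)
}

#' Y-randomization control
#'
#' Permutes the labels (seeded) and reruns the identical validation
#' protocol. On informative data the mean MCC collapses toward 0,
#' showing the unpermuted model is not a chance correlation.
#'
#' @inheritParams mqc_validate
#' @param perm_seed seed for the label permutation.
#' @return `mqc_validation` on the permuted labels.
#' @export
y_randomization <- function(x, y, proportions = seq(0.05, 0.80, by = 0.05),
                            n_splits = 200, seed = 1, perm_seed = seed, ...) {
  set.seed(perm_seed)
  y_perm <- sample(y)
  mqc_validate(x, y_perm, proportions = proportions, n_splits = n_splits,
               seed = seed, ...)
}
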