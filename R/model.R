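# ---- internal: portable decision trees -------------------------------
#
# The boosting weak learner is a depth-limited CART with the weighted
# Gini criterion, fitted by exhaustive vectorized threshold search and
# stored directly as a plain node table (node number, split variable,
# split point, leaf class). The boosting loop refits thousands of small
# weighted trees, so the fitter works on pre-extracted matrices with no
# model-frame machinery, and the node-table form makes persisted models
# self-contained. Ties are broken deterministically (first feature,
# lowest threshold, lowest class index).

fit_cart <- function(Xs, Os, y, w, K, max_depth = 3, min_split = 4,
                     min_bucket = 2) {
  # Xs[[j]]: feature j pre-sorted ascending; Os[[j]]: the row indices in
  # that order (computed once per ensemble, reused across stages)
  p <- length(Xs)
  n_all <- length(y)
  max_nodes <- 2L^(max_depth + 1L) - 1L
  nd_node <- integer(0); nd_var <- integer(0)
  nd_split <- numeric(0); nd_cls <- integer(0)
  importance <- numeric(p)
  grow <- function(node_id, member, depth) {
    wk <- numeric(K)
    sel_y <- y[member]; sel_w <- w[member]
    for (k in seq_len(K)) wk[k] <- sum(sel_w[sel_y == k])
    cls <- which.max(wk)
    wtot <- sum(wk)
    n <- length(sel_y)
    emit <- function(var, split) {
      nd_node[length(nd_node) + 1L] <<- node_id
      nd_var[length(nd_var) + 1L] <<- var
      nd_split[length(nd_split) + 1L] <<- split
      nd_cls[length(nd_cls) + 1L] <<- cls
    }
    if (depth >= max_depth || n < min_split || sum(wk > 0) == 1L ||
        wtot <= 0) return(emit(0L, NA_real_))
    base <- sum(wk^2) / wtot
    best_gain <- 1e-12; best_var <- 0L; best_thr <- NA_real_
    memb <- logical(n_all); memb[member] <- TRUE
    for (j in seq_len(p)) {
      keep <- memb[Os[[j]]]
      xs <- Xs[[j]][keep]
      oj <- Os[[j]][keep]
      ws <- w[oj]; ys <- y[oj]
      wl <- cumsum(ws)
      suml2 <- 0; sumr2 <- 0
      for (k in seq_len(K)) {
        cw <- cumsum(ws * (ys == k))
        suml2 <- suml2 + cw^2
        sumr2 <- sumr2 + (wk[k] - cw)^2
      }
      pos <- seq_len(n - 1L)
      wlp <- wl[pos]; wrp <- wtot - wlp
      ok <- xs[pos] < xs[pos + 1L] & pos >= min_bucket &
        (n - pos) >= min_bucket & wlp > 0 & wrp > 0
      if (!any(ok)) next
      crit <- suml2[pos] / wlp + sumr2[pos] / wrp
      crit[!ok] <- -Inf
      i <- which.max(crit)
      gain <- crit[i] - base
      if (gain > best_gain + 1e-12) {
        best_gain <- gain; best_var <- j
        best_thr <- (xs[i] + xs[i + 1L]) / 2
      }
    }
    if (best_var == 0L) return(emit(0L, NA_real_))
    importance[best_var] <<- importance[best_var] + best_gain
    emit(best_var, best_thr)
    keep <- memb[Os[[best_var]]]
    oj <- Os[[best_var]][keep]
    go_left <- Xs[[best_var]][keep] < best_thr
    grow(2L * node_id, oj[go_left], depth + 1L)
    grow(2L * node_id + 1L, oj[!go_left], depth + 1L)
  }
  grow(1L, seq_len(n_all), 0L)
  list(nodes = list(node = nd_node, var = nd_var, split = nd_split,
                    dir_lt = rep(TRUE, length(nd_node)), cls = nd_cls),
       importance = importance)
}

nodes_predict <- function(nodes, X) {
  # X: numeric matrix, columns in feature order
  cur <- rep(1L, nrow(X))
  pos <- match(cur, nodes$node)
  repeat {
    open <- nodes$var[pos] != 0L
    if (!any(open)) break
    v <- nodes$var[pos[open]]
    x <- X[cbind(which(open), v)]
    left <- ifelse(nodes$dir_lt[pos[open]],
                   x < nodes$split[pos[open]],
                   x >= nodes$split[pos[open]])
    cur[open] <- 2L * cur[open] + ifelse(left, 0L, 1L)
    pos <- match(cur, nodes$node)
  }
  nodes$cls[pos]
}

samme_fit <- function(X, y, n_stages, max_depth, learning_rate,
                      feature_names) {
  n <- nrow(X); K <- nlevels(y)
  yi <- as.integer(y)
  w <- rep(1 / n, n)
  Os <- lapply(seq_len(ncol(X)), function(j) order(X[, j], method = "radix"))
  Xs <- lapply(seq_len(ncol(X)), function(j) X[Os[[j]], j])
  trees <- list(); alphas <- numeric(0)
  importance <- stats::setNames(numeric(length(feature_names)), feature_names)
  eps <- 1e-10
  for (m in seq_len(n_stages)) {
    fit <- fit_cart(Xs, Os, yi, w, K, max_depth = max_depth)
    h <- nodes_predict(fit$nodes, X)
    mis <- h != yi
    err <- sum(w[mis])
    if (err >= 1 - 1 / K) break        # weak learner no better than chance
    err <- max(err, eps)
    alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
    trees[[length(trees) + 1L]] <- fit$nodes
    alphas <- c(alphas, alpha)
    importance <- importance + alpha * fit$importance
    if (err <= eps) break              # perfect stage: voting is settled
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  if (!length(trees))
    stop("boosting failed: no stage beat chance")
  list(trees = trees, alphas = alphas, importance = importance)
}

samme_prob <- function(ensemble, X, K) {
  votes <- matrix(0, nrow(X), K)
  for (m in seq_along(ensemble$trees)) {
    h <- nodes_predict(ensemble$trees[[m]], X)
    votes[cbind(seq_len(nrow(X)), h)] <-
      votes[cbind(seq_len(nrow(X)), h)] + ensemble$alphas[m]
  }
  votes / sum(ensemble$alphas)
}

# population standard deviation of a probability vector (rows of p);
# bounded by sd(1,0,...,0) = sqrt((K-1))/K
prob_spread <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  mu <- rowMeans(p)
  sqrt(rowMeans((p - mu)^2))
}

# ---- fitting ----------------------------------------------------------

#' Fit the matrix-level QC classifier
#'
#' Trains a multiclass boosted-tree model (SAMME-style AdaBoost of
#' depth-limited CART trees) mapping the seven block features to the
#' Good/Medium/Bad quality grade, and calibrates a confidence score from
#' the spread of the class probabilities via seeded cross-validation:
#' the per-case 0/1 error of held-out predictions is regressed on the
#' probability spread (local polynomial fit, clipped and made monotone),
#' and confidence is one minus that expected error.
#'
#' @param x data.frame containing the feature columns named in
#'   `feature_names` (extra columns such as `block_id` are ignored).
#' @param y class labels; coerced to a factor. With the canonical
#'   Good/Medium/Bad labels the level order Good, Medium, Bad is used.
#' @param n_stages boosting stages (default 100).
#' @param max_depth tree depth limit (default 3).
#' @param learning_rate shrinkage applied to stage weights (default 0.5).
#' @param seed seed for the calibration folds.
#' @param calibrate fit the confidence curve by `cal_folds`-fold
#'   cross-validation (default TRUE).
#' @param cal_folds folds used for calibration (default 5).
#' @return an object of class `mqc`: the ensemble, alpha-weighted feature
#'   importances, hyperparameters and the calibration curve.
#' @examples
#' tr <- gen_training_blocks(n_good = 20, n_medium = 20, n_bad = 20, seed = 1)
#' fx <- qc_features(tr$blocks, features_control(n_perm = 99, n_boot = 99, seed = 1))
#' fit <- mqc(fx, tr$labels, seed = 1)
#' predict(fit, fx[1:3, ])
#' @export
mqc <- function(x, y, n_stages = 100, max_depth = 3, learning_rate = 0.5,
                seed = 1, calibrate = TRUE, cal_folds = 5) {
  feature_names <- MQC_FEATURES
  miss <- setdiff(feature_names, names(x))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(x[feature_names])
  if (anyNA(X) || any(!is.finite(X))) stop("features contain missing values")
  y <- canonical_labels(y)
  if (nlevels(y) < 2) stop("need at least 2 classes to train")
  ens <- samme_fit(X, y, n_stages, max_depth, learning_rate, feature_names)
  model <- structure(
    list(ensemble = ens, feature_names = feature_names,
         classes = levels(y),
         hyperparams = list(n_stages = n_stages, max_depth = max_depth,
                            learning_rate = learning_rate, seed = seed),
         calibration = NULL,
         global_error = NA_real_),
    class = "mqc")
  if (calibrate) {
    oos <- cv_oos_predictions(X, y, n_stages, max_depth, learning_rate,
                              feature_names, cal_folds, seed)
    model <- set_calibration(model, oos$spread, oos$wrong)
  }
  model
}

canonical_labels <- function(y) {
  y <- as.character(y)
  canon <- c("Good", "Medium", "Bad")
  if (all(y %in% canon)) factor(y, levels = intersect(canon, unique(y)))
  else factor(y)
}

cv_oos_predictions <- function(X, y, n_stages, max_depth, learning_rate,
                               feature_names, folds, seed) {
  set.seed(seed)
  n <- nrow(X)
  fold <- integer(n)
  for (k in levels(y)) {          # stratified fold assignment
    idx <- which(y == k)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  spread <- numeric(n); wrong <- logical(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    ens <- samme_fit(X[tr, , drop = FALSE], droplevels(y[tr]), n_stages,
                     max_depth, learning_rate, feature_names)
    p <- samme_prob(ens, X[!tr, , drop = FALSE], nlevels(droplevels(y[tr])))
    lab <- levels(droplevels(y[tr]))[max.col(p, ties.method = "first")]
    spread[!tr] <- prob_spread(p)
    wrong[!tr] <- lab != as.character(y[!tr])
  }
  list(spread = spread, wrong = wrong)
}

# ---- confidence calibration -------------------------------------------

#' Calibrate the confidence curve from out-of-sample predictions
#'
#' Local polynomial regression (loess) of the 0/1 classification-error
#' indicator on the class-probability spread, clipped to `[0, 1]` and
#' made monotone non-increasing by isotonic post-smoothing. With fewer
#' than 30 points the curve falls back to the constant global error
#' rate (with a warning). The model's confidence for a prediction with
#' spread s is `1 - curve(s)`.
#'
#' @param model a fitted `mqc` model.
#' @param x out-of-sample feature data.frame.
#' @param y true labels for `x`.
#' @return the model with an updated calibration curve.
#' @export
mqc_calibrate <- function(model, x, y) {
  p <- predict(model, x)
  y <- as.character(y)
  set_calibration(model, p$prob_sd, p$label != y)
}

set_calibration <- function(model, spread, wrong) {
  err <- as.numeric(wrong)
  model$global_error <- mean(err)
  smax <- sqrt(length(model$classes) - 1) / length(model$classes)
  grid <- seq(0, smax, length.out = 101)
  if (length(spread) < 30) {
    warning("fewer than 30 out-of-sample predictions; using constant error rate")
    model$calibration <- list(x = grid, y = rep(mean(err), length(grid)))
    return(model)
  }
  if (stats::sd(spread) < 1e-8) {
    # all predictions equally decisive: nothing to regress on
    model$calibration <- list(x = grid, y = rep(mean(err), length(grid)))
    return(model)
  }
  # local polynomial fit; loess warns on near-singular neighborhoods when
  # spreads pile up at the decisive end, which is harmless here
  fit <- tryCatch(
    suppressWarnings(stats::loess(
      err ~ spread, degree = 2,
      control = stats::loess.control(surface = "direct"))),
    error = function(e) NULL)
  if (is.null(fit)) {
    model$calibration <- list(x = grid, y = rep(mean(err), length(grid)))
    return(model)
  }
  # evaluate at the observed spreads only: the isotonic projection is
  # then weighted by where the data actually lives, and beyond the
  # observed support the curve continues at its boundary value (local
  # regression extrapolates wildly, with no data out there to learn from)
  xs <- sort(unique(spread))
  yhat <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(spread = xs)))
  yhat[is.na(yhat)] <- mean(err)
  yhat <- pmin(pmax(yhat, 0), 1)
  # enforce error non-increasing in spread (confidence non-decreasing)
  iso <- stats::isoreg(xs, -yhat)
  ys <- pmin(pmax(-iso$yf, 0), 1)
  cal <- stats::approx(xs, ys, xout = grid, rule = 2)
  model$calibration <- list(x = grid, y = cal$y)
  model
}

confidence_at <- function(model, spread) {
  if (is.null(model$calibration)) {
    if (is.na(model$global_error)) return(rep(NA_real_, length(spread)))
    return(rep(1 - model$global_error, length(spread)))
  }
  err <- stats::approx(model$calibration$x, model$calibration$y,
                       xout = spread, rule = 2)$y
  1 - err
}

# ---- prediction and methods -------------------------------------------

#' Predict quality grades for blocks
#'
#' @param object a fitted `mqc` model.
#' @param newdata data.frame with the model's feature columns (a
#'   `block_id` column, if present, is carried through).
#' @param ... unused.
#' @return data.frame of class `mqc_prediction`: `label`, one
#'   `prob_<class>` column per class, `prob_sd` (population sd of the
#'   class probabilities) and calibrated `confidence`.
#' @export
predict.mqc <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop("feature schema mismatch: newdata lacks ",
         paste(miss, collapse = ", "))
  X <- as.matrix(newdata[object$feature_names])
  if (anyNA(X)) stop("missing feature values in newdata")
  p <- samme_prob(object$ensemble, X, length(object$classes))
  colnames(p) <- paste0("prob_", object$classes)
  spread <- prob_spread(p)
  out <- data.frame(
    label = object$classes[max.col(p, ties.method = "first")],
    p, prob_sd = spread,
    confidence = confidence_at(object, spread))
  if (!is.null(newdata$block_id))
    out <- cbind(block_id = newdata$block_id, out)
  class(out) <- c("mqc_prediction", "data.frame")
  out
}

#' @export
print.mqc <- function(x, ...) {
  cat(sprintf("<mqc> %d-class boosted-tree QC model (%d stages, depth %d, lr %.2f)\n",
              length(x$classes), length(x$ensemble$alphas),
              x$hyperparams$max_depth, x$hyperparams$learning_rate))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  calibrated:", !is.null(x$calibration), "\n")
  invisible(x)
}

#' @export
summary.mqc <- function(object, ...) {
  imp <- sort(object$ensemble$importance, decreasing = TRUE)
  structure(list(model = object,
                 importance = 100 * imp / sum(imp),
                 global_error = object$global_error),
            class = "summary.mqc")
}

#' @export
print.summary.mqc <- function(x, ...) {
  print(x$model)
  cat("  relative feature importance (%):\n")
  for (nm in names(x$importance))
    cat(sprintf("    %-12s %6.2f\n", nm, x$importance[nm]))
  if (!is.na(x$global_error))
    cat(sprintf("  cross-validated error rate: %.3f\n", x$global_error))
  invisible(x)
}

#' @export
plot.mqc <- function(x, ...) {
  if (is.null(x$calibration)) stop("model has no calibration curve")
  plot(x$calibration$x, 1 - x$calibration$y, type = "l",
       xlab = "class-probability spread",
       ylab = "confidence (1 - expected error)", ylim = c(0, 1), ...)
  invisible(x)
}

# ---- persistence -------------------------------------------------------

#' Persist a fitted model as self-describing JSON
#'
#' The document carries the exported stage trees, stage weights,
#' calibration knots, hyperparameters, class and feature names, and a
#' format version, so a saved model is fully portable.
#'
#' @param model fitted `mqc`.
#' @param path output file.
#' @export
write_mqc <- function(model, path) {
  doc <- list(format = "mqc-model", version = 1L,
              feature_names = model$feature_names,
              classes = model$classes,
              hyperparams = model$hyperparams,
              alphas = model$ensemble$alphas,
              importance = as.list(model$ensemble$importance),
              trees = lapply(model$ensemble$trees, as.list),
              calibration = model$calibration,
              global_error = model$global_error)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_mqc
#' @export
read_mqc <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "mqc-model"))
    stop("not an mqc model document")
  trees <- lapply(doc$trees, function(tr) {
    d <- as.data.frame(tr)
    d$node <- as.integer(d$node); d$var <- as.integer(d$var)
    d$cls <- as.integer(d$cls)
    d
  })
  cal <- if (is.null(doc$calibration)) NULL
         else list(x = doc$calibration$x, y = doc$calibration$y)
  structure(list(
    ensemble = list(trees = trees, alphas = doc$alphas,
                    importance = unlist(doc$importance)),
    feature_names = doc$feature_names,
    classes = doc$classes,
    hyperparams = doc$hyperparams,
    calibration = cal,
    global_error = if (is.null(doc$global_error)) NA_real_ else doc$global_error),
    class = "mqc")
}
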