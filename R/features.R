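#' Feature-extraction settings
#'
#' Tunable parameters shared by the block-level feature computations.
#'
#' @param n_perm permutations for the Moran's I test (default 999).
#' @param n_boot bootstrap resamples for the smoothness test (default
#'   10000, the value used for production feature extraction; tests and
#'   interactive work usually pass something smaller).
#' @param seed integer seed making the two resampling features
#'   reproducible.
#' @param rsd_cap value reported for a relative standard deviation whose
#'   mean is numerically zero (default 1000).
#' @param moran_method `"permutation"` or `"analytic"` (normal
#'   approximation, much faster, no resampling).
#' @param moran_alternative `"greater"` tests for positive spatial
#'   autocorrelation (small p = smooth landscape, the orientation the
#'   classifier is trained with); `"less"` flips it.
#' @param smooth_refit if TRUE, re-estimate the surface smoothing
#'   parameter for every bootstrap resample instead of holding the
#'   smoother fixed at the observed fit (slow; see the methods vignette).
#' @export
features_control <- function(n_perm = 999, n_boot = 10000, seed = NULL,
                             rsd_cap = 1000,
                             moran_method = c("permutation", "analytic"),
                             moran_alternative = c("greater", "less"),
                             smooth_refit = FALSE) {
  list(n_perm = n_perm, n_boot = n_boot, seed = seed, rsd_cap = rsd_cap,
       moran_method = match.arg(moran_method),
       moran_alternative = match.arg(moran_alternative),
       smooth_refit = smooth_refit)
}

#' Canonical feature names, in order
#' @export
MQC_FEATURES <- c("dmso.v", "sa.min", "sa.max", "sa.matrix",
                  "moran.p", "smoothness.p", "mono.v")

#' Negative-control level of a block
#'
#' Normalized response at the DMSO corner (N, N). For signal-increasing
#' readouts (e.g. Caspase-Glo, where the positive control raises the
#' signal) the value is re-oriented as `100 - response` so that 100 always
#' means "control behaved as expected".
#'
#' @param block a `response_block`.
#' @return percent.
#' @export
dmso_v <- function(block) {
  v <- block$responses[block$n, block$n]
  if (block$readout_direction == "signal_increasing") 100 - v else v
}

# 100 * sample sd / |mean|, with a cap when the mean is numerically zero
rsd <- function(x, cap = 1000) {
  m <- abs(mean(x))
  if (m < 1e-9) {
    warning("RSD mean numerically zero; reporting cap")
    return(cap)
  }
  100 * stats::sd(x) / m
}

#' Single-agent and combination-submatrix relative standard deviations
#'
#' `single_agent_rsds()` computes the RSD (100 * sd / |mean|) of each
#' single-agent dose-response edge and returns the pair sorted as
#' `(sa.min, sa.max)`. `submatrix_rsd()` does the same over the
#' `(N-1) x (N-1)` combination submatrix. Low RSD flags a flat (often
#' dead or inactive) response; the classifier learns how much variance a
#' credible block carries.
#'
#' @param block a `response_block`.
#' @param cap reported value when a mean is numerically zero.
#' @return `single_agent_rsds()`: named numeric `c(sa.min, sa.max)`;
#'   `submatrix_rsd()`: a single percent value.
#' @export
single_agent_rsds <- function(block, cap = 1000) {
  sa <- single_agent_responses(block)
  r1 <- rsd(sa$agent1, cap)
  r2 <- rsd(sa$agent2, cap)
  c(sa.min = min(r1, r2), sa.max = max(r1, r2))
}

#' @rdname single_agent_rsds
#' @export
submatrix_rsd <- function(block, cap = 1000) {
  rsd(as.vector(combo_submatrix(block)), cap)
}

# Row-standardized rook-adjacency weight matrix for an nr x nc grid,
# cells in column-major order.
rook_weights <- function(nr, nc) {
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  from <- integer(0); to <- integer(0)
  if (nr > 1) {
    a <- idx[-nr, , drop = FALSE]; b <- idx[-1, , drop = FALSE]
    from <- c(from, a, b); to <- c(to, b, a)
  }
  if (nc > 1) {
    a <- idx[, -nc, drop = FALSE]; b <- idx[, -1, drop = FALSE]
    from <- c(from, a, b); to <- c(to, b, a)
  }
  w <- matrix(0, n, n)
  w[cbind(from, to)] <- 1
  w / rowSums(w)
}

#' Moran's I on a grid
#'
#' Classical Moran's I with row-standardized rook (shared-edge) adjacency
#' weights. Under no spatial autocorrelation its expectation is
#' `-1/(n-1)` where n is the number of cells.
#'
#' @param grid numeric matrix.
#' @return Moran's I (dimensionless).
#' @export
moran_i <- function(grid) {
  z <- as.vector(grid) - mean(grid)
  denom <- sum(z^2)
  if (denom == 0) stop("zero variance: Moran's I undefined on constant grid")
  w <- rook_weights(nrow(grid), ncol(grid))
  # row-standardized weights: S0 = n, so the n/S0 factor cancels
  as.numeric(crossprod(z, w %*% z) / denom)
}

#' Moran's I spatial-autocorrelation test on the combination submatrix
#'
#' One-sided test for positive spatial autocorrelation: small p means the
#' response landscape is spatially organized (smooth), large p means
#' spatially random. The permutation null resamples cell positions; the
#' analytic variant uses the normality approximation for speed.
#'
#' @param block a `response_block` (the test runs on its combination
#'   submatrix), or a plain matrix.
#' @param control [features_control()] list (n_perm, seed, method,
#'   alternative).
#' @return p-value in `[1/(1+n_perm), 1]` (permutation) or `(0, 1)`
#'   (analytic). Constant grids return 1 with a warning.
#' @export
moran_test <- function(block, control = features_control()) {
  grid <- if (inherits(block, "response_block")) combo_submatrix(block) else block
  z <- as.vector(grid) - mean(grid)
  if (sum(z^2) == 0) {
    warning("constant grid: no spatial signal assessable, p = 1")
    return(1)
  }
  i_obs <- moran_i(grid)
  n <- length(z)
  if (control$moran_method == "analytic") {
    w <- rook_weights(nrow(grid), ncol(grid))
    s0 <- sum(w)
    s1 <- 0.5 * sum((w + t(w))^2)
    s2 <- sum((rowSums(w) + colSums(w))^2)
    ei <- -1 / (n - 1)
    vi <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - ei^2
    zscore <- (i_obs - ei) / sqrt(vi)
    p <- stats::pnorm(zscore, lower.tail = FALSE)
    if (control$moran_alternative == "less") p <- 1 - p
    return(p)
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  w <- rook_weights(nrow(grid), ncol(grid))
  denom <- sum(z^2)
  zperm <- vapply(seq_len(control$n_perm),
                  function(k) { zp <- z[sample.int(n)]
                                as.numeric(crossprod(zp, w %*% zp)) / denom },
                  0)
  extreme <- if (control$moran_alternative == "greater") zperm >= i_obs
             else zperm <= i_obs
  (1 + sum(extreme)) / (1 + control$n_perm)
}

#' Smoothness test of the activity landscape
#'
#' Fits a two-dimensional penalized additive surface (tensor-product
#' spline, smoothing chosen by GCV via \pkg{mgcv}) to the block responses
#' over grid coordinates, and measures the RMSD between fitted and
#' observed values: a smooth landscape fits nearly perfectly (RMSD close
#' to 0), a rugged one does not. The null distribution is built by
#' resampling the cell values with replacement onto grid positions
#' (`n_boot` times) and refitting; the p-value is the probability that
#' such a random, usually rugged, landscape has an RMSD no larger than
#' the observed one (add-one smoothing). Small p = smooth.
#'
#' By default the null refits reuse the smoother estimated on the
#' observed data (an influence-matrix projection), making 10,000
#' resamples essentially free; `smooth_refit = TRUE` re-runs the full GCV
#' fit per resample.
#'
#' @param block a `response_block` (the full N x N grid is fitted) or a
#'   plain matrix.
#' @param control [features_control()] (n_boot, seed, smooth_refit).
#' @return p-value in `[1/(1+n_boot), 1]`; constant blocks return 1 with
#'   a warning.
#' @export
smoothness_test <- function(block, control = features_control()) {
  grid <- if (inherits(block, "response_block")) block$responses else block
  y <- as.vector(grid)
  if (stats::sd(y) == 0) {
    warning("constant block: smoothness not assessable, p = 1")
    return(1)
  }
  nr <- nrow(grid); nc <- ncol(grid)
  d <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  d <- d[order(d$j, d$i), ]        # column-major, matches as.vector
  d$y <- y
  k <- c(max(3, min(5, nr - 1)), max(3, min(5, nc - 1)))
  fit <- mgcv::gam(y ~ te(i, j, k = k), data = d)
  rmsd_obs <- sqrt(mean((y - stats::fitted(fit))^2))
  if (!is.null(control$seed)) set.seed(control$seed)
  nb <- control$n_boot
  if (isTRUE(control$smooth_refit)) {
    rmsd_null <- vapply(seq_len(nb), function(b) {
      d$y <- sample(y, replace = TRUE)
      fb <- mgcv::gam(y ~ te(i, j, k = k), data = d)
      sqrt(mean((d$y - stats::fitted(fb))^2))
    }, 0)
  } else {
    X <- stats::predict(fit, type = "lpmatrix")
    # smoother (influence) matrix from the penalized normal equations,
    # stable even when the surface fits exactly (zero residual variance)
    St <- matrix(0, ncol(X), ncol(X))
    i_sp <- 0L
    for (sm in fit$smooth) {
      idx <- sm$first.para:sm$last.para
      for (S in sm$S) {
        i_sp <- i_sp + 1L
        St[idx, idx] <- St[idx, idx] + fit$sp[i_sp] * S
      }
    }
    A <- X %*% solve(crossprod(X) + St, t(X))
    Ystar <- matrix(sample(y, length(y) * nb, replace = TRUE),
                    length(y), nb)
    R <- Ystar - A %*% Ystar
    rmsd_null <- sqrt(colMeans(R^2))
  }
  (1 + sum(rmsd_null <= rmsd_obs)) / (1 + nb)
}

# precomputed comparable ordered-pair index for an m x m submatrix:
# pair (p, q) with q at equal-or-higher dose of both agents (lower or
# equal row AND column index), at least one strictly lower
mono_pairs <- function(m) {
  idx <- expand.grid(i = seq_len(m), j = seq_len(m))
  n <- nrow(idx)
  p <- rep(seq_len(n), each = n)
  q <- rep(seq_len(n), times = n)
  keep <- idx$i[q] <= idx$i[p] & idx$j[q] <= idx$j[p] &
    !(idx$i[q] == idx$i[p] & idx$j[q] == idx$j[p])
  list(p = p[keep], q = q[keep],
       cell = cbind(idx$i, idx$j))
}

#' Likelihood of monotone dose response
#'
#' Over all ordered pairs of distinct combination-submatrix wells where
#' the second well has equal-or-higher dose of both agents (and strictly
#' higher of at least one), scores 1 when the response moves in the
#' pharmacologically expected direction (down for signal-decreasing
#' readouts, up for signal-increasing ones), 0 when it moves the opposite
#' way, and 0.5 on an exact tie. `mono.v` is the mean score: 1 for a
#' perfectly monotone landscape, 0 for a perfectly inverted one, and 0.5
#' in expectation for random responses. Because every comparable pair
#' contributes, local violations of monotonicity are tolerated.
#'
#' @param block a `response_block`.
#' @return likelihood in `[0, 1]`.
#' @export
mono_v <- function(block) {
  sub <- combo_submatrix(block)
  m <- nrow(sub)
  pp <- mono_pairs(m)
  vp <- sub[pp$cell[pp$p, , drop = FALSE]]
  vq <- sub[pp$cell[pp$q, , drop = FALSE]]
  # expected: higher dose (q) lowers the signal for signal_decreasing
  if (block$readout_direction == "signal_increasing") { tmp <- vp; vp <- vq; vq <- tmp }
  mean((vq < vp) + 0.5 * (vq == vp))
}

#' Compute the 7-feature vector of a block
#'
#' Assembles `dmso.v`, `sa.min`, `sa.max`, `sa.matrix`, `moran.p`,
#' `smoothness.p` and `mono.v` into one named row. Degenerate inputs are
#' downgraded to warnings with documented sentinels (p = 1 on constant
#' grids) so feature extraction never aborts a screen.
#'
#' @param block a `response_block`, or a list of them.
#' @param control [features_control()].
#' @return one-row data.frame per block (rows bound together for a list),
#'   with `block_id` as first column.
#' @export
qc_features <- function(block, control = features_control()) {
  if (!inherits(block, "response_block")) {
    out <- do.call(rbind, lapply(block, qc_features, control = control))
    rownames(out) <- NULL
    return(out)
  }
  sa <- single_agent_rsds(block, cap = control$rsd_cap)
  out <- data.frame(
    block_id = block$block_id,
    dmso.v = dmso_v(block),
    sa.min = unname(sa["sa.min"]),
    sa.max = unname(sa["sa.max"]),
    sa.matrix = submatrix_rsd(block, cap = control$rsd_cap),
    moran.p = moran_test(block, control),
    smoothness.p = smoothness_test(block, control),
    mono.v = mono_v(block))
  out
}

#' Four-parameter logistic (Hill) fit of a single-agent dose response
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x/ic50)^slope)`
#' via Levenberg-Marquardt, initialized at top = max response, bottom =
#' min response, ic50 = geometric mid-concentration, slope = 1. The fit
#' is `valid` only when it converged and the IC50 lies inside the tested
#' concentration range, matching the classic "valid IC50" heuristic.
#'
#' @param conc positive concentrations (the zero-dose anchor is excluded
#'   before fitting).
#' @param response responses (%) at those concentrations.
#' @return list of class `hill_fit`: `top`, `bottom`, `ic50`, `slope`,
#'   `rmse`, `valid`, `converged`.
#' @export
fit_hill <- function(conc, response) {
  keep <- conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(conc) < 4) stop("need at least 4 positive-dose points")
  invalid <- list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                  slope = NA_real_, rmse = NA_real_, valid = FALSE,
                  converged = FALSE)
  if (stats::sd(response) == 0)
    return(structure(invalid, class = "hill_fit"))
  start <- list(top = max(response), bottom = min(response),
                ic50 = exp(mean(log(range(conc)))), slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (conc / ic50)^slope),
      start = start,
      lower = c(top = -Inf, bottom = -Inf, ic50 = min(conc) / 1e3,
                slope = 0.05),
      upper = c(top = Inf, bottom = Inf, ic50 = max(conc) * 1e3,
                slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(invalid, class = "hill_fit"))
  p <- as.list(stats::coef(fit))
  rmse <- sqrt(mean(stats::resid(fit)^2))
  # a flat "fit" (top ~ bottom) carries no dose-response information
  informative <- abs(p$top - p$bottom) > 1e-6 * max(1, abs(p$top))
  structure(list(top = p$top, bottom = p$bottom, ic50 = p$ic50,
                 slope = p$slope, rmse = rmse,
                 valid = informative && p$ic50 >= min(conc) &&
                   p$ic50 <= max(conc),
                 converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<hill_fit> top=%.2f bottom=%.2f ic50=%.3g slope=%.2f rmse=%.2f valid=%s\n",
                x$top, x$bottom, x$ic50, x$slope, x$rmse, x$valid))
  else cat("<hill_fit> did not converge (invalid)\n")
  invisible(x)
}

#' Legacy heuristic matrix QC score
#'
#' Weighted sum of violated heuristic criteria from the earlier
#' matrix-QC recipe: (1) negative-control response within an accepted
#' range, (2) valid IC50 for both single-agent dose responses, (3) both
#' single-agent RSDs above 20, (4) combination-submatrix RSD above 25,
#' (5) Moran's I p-value below 0.05. Each violated criterion adds its
#' weight; larger scores mean worse blocks (with the default equal
#' weights of 5, a score above 10 means three or more violations).
#'
#' @param block a `response_block`.
#' @param weights 5-vector of non-negative criterion weights.
#' @param dmso_range accepted `dmso.v` range for criterion 1.
#' @param control [features_control()] for the Moran test.
#' @return list: `score`, logical `violated` (length 5), `features` used.
#' @export
mott_qc <- function(block, weights = rep(5, 5), dmso_range = c(80, 120),
                    control = features_control()) {
  stopifnot(length(weights) == 5, all(weights >= 0))
  sa <- single_agent_rsds(block, cap = control$rsd_cap)
  edges <- single_agent_responses(block)
  n <- block$n
  h1 <- fit_hill(block$conc1[-n], edges$agent1)
  h2 <- fit_hill(block$conc2[-n], edges$agent2)
  dv <- dmso_v(block)
  violated <- c(
    dmso = dv < dmso_range[1] || dv > dmso_range[2],
    ic50 = !(h1$valid && h2$valid),
    sa_rsd = !(sa["sa.min"] > 20),
    matrix_rsd = !(submatrix_rsd(block, cap = control$rsd_cap) > 25),
    moran = !(moran_test(block, control) < 0.05))
  list(score = sum(weights[violated]), violated = violated,
       hill = list(agent1 = h1, agent2 = h2))
}
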