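#' Normalized delta-Bliss of a combination block
#'
#' Under Bliss independence two non-interacting agents with fractional
#' inhibitions `fA` and `fB` combine to the expected inhibition
#' `C = fA + fB - fA * fB`. With viability-style normalization (100% =
#' no killing, 0% = full kill) the observed inhibition of well (i, j) is
#' `f = 1 - V/100`, clamped to `[0, 1]`. The per-well deviation is
#' `delta(i, j) = C(i, j) - f(i, j)` and DBNorm is its mean over the
#' combination submatrix, so DBNorm lies in `[-1, 1]`.
#'
#' Orientation: negative DBNorm means the observed killing exceeds the
#' Bliss expectation (synergy); positive means it falls short
#' (antagonism). Under this orientation a block of i.i.d. uniform random
#' responses has expected DBNorm 1/4 (each of fA, fB, f is uniform on
#' [0, 1], so E[C] - E[f] = 3/4 - 1/2), the fixed point that makes
#' heavily randomized screens drift toward apparent antagonism.
#'
#' @param block a `response_block` normalized as % viability.
#' @param clamp clamp inhibition fractions to `[0, 1]` (default TRUE;
#'   FALSE is a diagnostic mode in which DBNorm may leave `[-1, 1]`).
#' @return list of class `synergy_bliss`: `dbnorm`, `delta_grid`
#'   ((N-1) x (N-1)), `fA`, `fB`, `bliss_grid`.
#' @export
bliss_dbnorm <- function(block, clamp = TRUE) {
  n <- block$n
  cl <- if (clamp) function(x) pmin(pmax(x, 0), 1) else identity
  f <- cl(1 - combo_submatrix(block) / 100)
  sa <- single_agent_responses(block)
  fA <- cl(1 - sa$agent1 / 100)           # agent 1 varies along rows
  fB <- cl(1 - sa$agent2 / 100)           # agent 2 varies along columns
  C <- outer(fA, fB, function(a, b) a + b - a * b)
  delta <- C - f
  structure(list(dbnorm = mean(delta), delta_grid = delta,
                 fA = fA, fB = fB, bliss_grid = C),
            class = "synergy_bliss")
}

#' @export
print.synergy_bliss <- function(x, ...) {
  cat(sprintf("<synergy_bliss> DBNorm = %.4f (negative = synergy, positive = antagonism)\n",
              x$dbnorm))
  invisible(x)
}

#' Gaddum non-interaction scale (highest single agent)
#'
#' The reference surface is the highest-single-agent prediction on the
#' viability scale, `P(i, j) = min(V_A(i), V_B(j))` (the stronger agent
#' alone already produces that much killing). gamma is the least-squares
#' scale between the observed combination surface and the reference:
#' `gamma = argmin_g sum (V_obs - g * P)^2 = sum(V_obs * P) / sum(P^2)`.
#' gamma < 1 indicates synergy (observed viability below the reference,
#' i.e. more killing), gamma > 1 antagonism, gamma = 1 non-interaction.
#'
#' @param block a `response_block` normalized as % viability.
#' @return gamma (positive dimensionless scale).
#' @export
hsa_gamma <- function(block) {
  sa <- single_agent_responses(block)
  P <- outer(sa$agent1, sa$agent2, pmin)
  if (sum(P^2) == 0) stop("no reference surface: HSA prediction identically 0")
  V <- combo_submatrix(block)
  sum(V * P) / sum(P^2)
}

#' Synergy table for a set of blocks
#'
#' @param blocks list of `response_block`.
#' @return data.frame `block_id`, `dbnorm`, `gamma` (`gamma` is NA where
#'   the reference surface is degenerate).
#' @export
synergy_table <- function(blocks) {
  if (inherits(blocks, "response_block")) blocks <- list(blocks)
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(block_id = b$block_id,
               dbnorm = bliss_dbnorm(b)$dbnorm,
               gamma = tryCatch(hsa_gamma(b), error = function(e) NA_real_))
  }))
}
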