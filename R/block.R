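#' Construct a combination response block
#'
#' A response block is one N x N grid of normalized responses (% of the
#' negative control) for a pair of agents crossed over descending dose
#' ladders. Well `(i, j)` carries doses `(conc1[i], conc2[j])`. By
#' convention the DMSO (zero-dose) control sits at the bottom-right corner
#' `(N, N)`, the bottom row holds agent-2 single-agent responses, the right
#' column holds agent-1 single-agent responses, and the top-left
#' `(N-1) x (N-1)` submatrix holds the dose combinations.
#'
#' @param responses numeric N x N matrix of normalized responses (%).
#' @param conc1,conc2 length-N dose ladders, strictly descending with the
#'   last entry 0 (the zero-dose edge). Units are the caller's (typically
#'   molar).
#' @param block_id identifier for the block.
#' @param readout_direction `"signal_decreasing"` when the positive control
#'   lowers the signal (CellTiter-Glo style viability readouts) or
#'   `"signal_increasing"` when it raises it (Caspase-Glo style readouts).
#' @param agent1_id,agent2_id agent identifiers.
#' @param metadata optional named list (cell line, screen id, ...).
#' @param check validate invariants on construction (default TRUE).
#' @return An object of class `response_block`.
#' @seealso [validate_block()], [qc_features()], [bliss_dbnorm()]
#' @examples
#' b <- gen_block("clean_additive", n = 6, seed = 1)$block
#' b
#' @export
response_block <- function(responses, conc1, conc2, block_id = "block",
                           readout_direction = c("signal_decreasing",
                                                 "signal_increasing"),
                           agent1_id = "agent1", agent2_id = "agent2",
                           metadata = list(), check = TRUE) {
  readout_direction <- match.arg(readout_direction)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  b <- structure(
    list(block_id = as.character(block_id),
         n = nrow(responses),
         responses = responses,
         conc1 = as.numeric(conc1),
         conc2 = as.numeric(conc2),
         readout_direction = readout_direction,
         agent1_id = as.character(agent1_id),
         agent2_id = as.character(agent2_id),
         metadata = metadata),
    class = "response_block")
  if (check) {
    v <- validate_block(b)
    if (length(v))
      stop("invalid response block: ", paste(v, collapse = "; "))
  }
  b
}

#' Validate a response block
#'
#' Checks the structural invariants of a block and returns a character
#' vector of human-readable violations (empty when the block is valid).
#' Violations are returned, never raised, so screens with malformed blocks
#' can be triaged rather than aborted.
#'
#' @param block a `response_block`.
#' @return character vector of violation descriptions; `character(0)` if
#'   the block is well formed.
#' @export
validate_block <- function(block) {
  v <- character(0)
  r <- block$responses
  n <- block$n
  if (!is.matrix(r) || nrow(r) != ncol(r))
    return("responses is not a square matrix")
  if (n < 4)
    v <- c(v, sprintf("matrix dimension %d below minimum 4", n))
  if (length(block$conc1) != n || length(block$conc2) != n) {
    v <- c(v, "concentration ladder length does not match matrix dimension")
    return(v)
  }
  for (ax in c("conc1", "conc2")) {
    cc <- block[[ax]]
    if (cc[n] != 0)
      v <- c(v, sprintf("%s[%d] is not 0 (zero-dose edge)", ax, n))
    head_cc <- cc[-n]
    if (any(head_cc <= 0) || any(diff(head_cc) >= 0))
      v <- c(v, sprintf("%s concentrations not strictly descending", ax))
  }
  bad <- which(!is.finite(r), arr.ind = TRUE)
  if (nrow(bad))
    v <- c(v, apply(bad, 1, function(ij)
      sprintf("non-finite response at (%d,%d)", ij[1], ij[2])))
  if (!block$readout_direction %in% c("signal_decreasing", "signal_increasing"))
    v <- c(v, "unknown readout direction")
  v
}

#' @export
print.response_block <- function(x, ...) {
  cat(sprintf("<response_block> %s: %dx%d, %s vs %s (%s)\n",
              x$block_id, x$n, x$n, x$agent1_id, x$agent2_id,
              x$readout_direction))
  cat(sprintf("  DMSO corner: %.1f%%; combination submatrix %dx%d\n",
              x$responses[x$n, x$n], x$n - 1L, x$n - 1L))
  invisible(x)
}

# combination submatrix (both agents dosed)
combo_submatrix <- function(block) {
  n <- block$n
  block$responses[seq_len(n - 1L), seq_len(n - 1L), drop = FALSE]
}

# single-agent edges: agent 1 lives in the right column, agent 2 in the
# bottom row (excluding the DMSO corner)
single_agent_responses <- function(block) {
  n <- block$n
  list(agent1 = block$responses[seq_len(n - 1L), n],
       agent2 = block$responses[n, seq_len(n - 1L)])
}

#' Read and write response blocks as long-format CSV
#'
#' The on-disk dialect is one row per well with header exactly
#' `block_id,row,col,conc1,conc2,response`. Wells of a block must form a
#' complete N x N grid.
#'
#' @param path CSV file path.
#' @param readout_direction readout orientation to attach to every block
#'   read (the dialect does not carry it).
#' @return `read_blocks()` returns a list of `response_block`.
#' @export
read_blocks <- function(path, readout_direction = "signal_decreasing") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("block_id", "row", "col", "conc1", "conc2", "response")
  if (!identical(names(d), want))
    stop("block CSV header mismatch: expected ", paste(want, collapse = ","),
         " got ", paste(names(d), collapse = ","))
  lapply(split(d, d$block_id), function(dd) {
    n <- max(dd$row)
    if (max(dd$col) != n || nrow(dd) != n * n)
      stop("block ", dd$block_id[1], " is not a complete square grid")
    m <- matrix(NA_real_, n, n)
    m[cbind(dd$row, dd$col)] <- dd$response
    c1 <- rep(NA_real_, n); c2 <- rep(NA_real_, n)
    c1[dd$row] <- dd$conc1
    c2[dd$col] <- dd$conc2
    response_block(m, c1, c2, block_id = dd$block_id[1],
                   readout_direction = readout_direction)
  })
}

#' @rdname read_blocks
#' @param blocks list of `response_block` objects (or a single one).
#' @export
write_blocks <- function(blocks, path) {
  if (inherits(blocks, "response_block")) blocks <- list(blocks)
  rows <- lapply(blocks, function(b) {
    idx <- expand.grid(row = seq_len(b$n), col = seq_len(b$n))
    data.frame(block_id = b$block_id, row = idx$row, col = idx$col,
               conc1 = b$conc1[idx$row], conc2 = b$conc2[idx$col],
               response = b$responses[cbind(idx$row, idx$col)])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Default geometric dose ladder
#'
#' N-point ladder: `top` followed by 1:`dilution` serial dilutions, with the
#' final entry 0 (the zero-dose edge the block geometry requires).
#'
#' @param n ladder length (block dimension).
#' @param top highest dose.
#' @param dilution fold dilution between steps (default 2).
#' @export
dose_ladder <- function(n, top = 1e-5, dilution = 2) {
  c(top / dilution^(0:(n - 2L)), 0)
}
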