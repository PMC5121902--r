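#' Microtiter plate with control roles and block map
#'
#' Holds raw (or normalized) well signals for a 384- (16 x 24) or 1536-well
#' (32 x 48) plate, together with the role of each well (`pos`, `neg`,
#' `sample`) and, for sample wells, the block each well belongs to and its
#' (row, col) position inside that block.
#'
#' @param plate_id identifier.
#' @param geometry `c(rows, cols)`; 16 x 24 and 32 x 48 are the supported
#'   formats.
#' @param wells data.frame with columns `row`, `col`, `signal`, `role` and
#'   optionally `block_id`, `block_row`, `block_col` (NA for control wells).
#' @return object of class `mqc_plate`.
#' @export
plate <- function(plate_id, geometry, wells) {
  stopifnot(length(geometry) == 2, all(geometry >= 1))
  need <- c("row", "col", "signal", "role")
  if (!all(need %in% names(wells)))
    stop("wells must have columns ", paste(need, collapse = ", "))
  for (nm in c("block_id", "block_row", "block_col"))
    if (is.null(wells[[nm]])) wells[[nm]] <- NA
  if (any(wells$row > geometry[1]) || any(wells$col > geometry[2]))
    stop("well coordinates outside plate geometry")
  if (anyDuplicated(wells[c("row", "col")]))
    stop("duplicated well coordinates")
  mapped <- !is.na(wells$block_id)
  if (any(mapped & wells$role != "sample"))
    stop("control wells cannot be mapped to blocks")
  key <- paste(wells$block_id[mapped], wells$block_row[mapped],
               wells$block_col[mapped])
  if (anyDuplicated(key))
    stop("a block position is mapped to more than one well")
  wells$well <- well_label(wells$row, wells$col)
  structure(list(plate_id = as.character(plate_id),
                 geometry = as.integer(geometry),
                 wells = wells),
            class = "mqc_plate")
}

#' @export
print.mqc_plate <- function(x, ...) {
  cat(sprintf("<mqc_plate> %s: %dx%d, %d wells (%d neg, %d pos, %d sample)\n",
              x$plate_id, x$geometry[1], x$geometry[2], nrow(x$wells),
              sum(x$wells$role == "neg"), sum(x$wells$role == "pos"),
              sum(x$wells$role == "sample")))
  invisible(x)
}

#' Well labels
#'
#' Converts between (row, col) coordinates and `"A01"`-style labels. Row
#' letters run A..Z then AA..AF (covering 32 rows); columns are
#' zero-padded to two digits.
#'
#' @param row,col 1-based coordinates.
#' @export
well_label <- function(row, col) {
  letters32 <- c(LETTERS, paste0("A", LETTERS[1:6]))
  sprintf("%s%02d", letters32[row], col)
}

#' @rdname well_label
#' @param label character well label(s).
#' @return `well_coords()` returns a data.frame with `row` and `col`.
#' @export
well_coords <- function(label) {
  letters32 <- c(LETTERS, paste0("A", LETTERS[1:6]))
  m <- regmatches(label, regexec("^([A-Z]+)([0-9]+)$", label))
  row <- match(vapply(m, `[`, "", 2), letters32)
  col <- as.integer(vapply(m, `[`, "", 3))
  if (anyNA(row) || anyNA(col)) stop("unparseable well label")
  data.frame(row = row, col = col)
}

#' Plate control summaries
#'
#' Means/SDs and medians/MADs of the positive and negative control wells,
#' the inputs to [zprime()] and [ssmd_robust()]. The MAD uses the 1.4826
#' normal-consistency scale factor.
#'
#' @param neg,pos numeric vectors of control signals, or pass `plate` to
#'   extract them by role.
#' @param plate an `mqc_plate`; used when `neg`/`pos` are missing.
#' @return object of class `control_stats`.
#' @export
control_stats <- function(neg, pos, plate = NULL) {
  if (!is.null(plate)) {
    neg <- plate$wells$signal[plate$wells$role == "neg"]
    pos <- plate$wells$signal[plate$wells$role == "pos"]
  }
  if (length(neg) < 2 || length(pos) < 2)
    stop("need at least 2 wells per control group")
  structure(list(
    neg = list(values = neg, mean = mean(neg), sd = stats::sd(neg),
               median = stats::median(neg), mad = stats::mad(neg)),
    pos = list(values = pos, mean = mean(pos), sd = stats::sd(pos),
               median = stats::median(pos), mad = stats::mad(pos)),
    n_neg = length(neg), n_pos = length(pos)),
    class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf("<control_stats> neg: %.3g +/- %.3g (n=%d); pos: %.3g +/- %.3g (n=%d)\n",
              x$neg$mean, x$neg$sd, x$n_neg, x$pos$mean, x$pos$sd, x$n_pos))
  invisible(x)
}

#' Normalize plate signals to percent of the control window
#'
#' Affine map `100 * (x - mu_pos) / (mu_neg - mu_pos)` applied to every
#' well: the negative-control mean maps to 100, the positive-control mean
#' to 0. Values outside [0, 100] are preserved, not clipped.
#'
#' @param plate an `mqc_plate` with raw signals.
#' @param stats optional [control_stats()]; defaults to the plate's own
#'   control wells.
#' @return the plate with `signal` replaced by the normalized percentage.
#' @export
normalize_plate <- function(plate, stats = NULL) {
  if (is.null(stats)) stats <- control_stats(plate = plate)
  window <- stats$neg$mean - stats$pos$mean
  if (!is.finite(window) || window == 0)
    stop("degenerate controls: zero normalization window")
  plate$wells$signal <- 100 * (plate$wells$signal - stats$pos$mean) / window
  plate
}

#' Deconvolute a plate into response blocks
#'
#' Collects the block-mapped wells of a (normalized) plate into
#' `response_block` objects. Every mapped block must be complete: each
#' (i, j) position of the declared N x N grid present exactly once.
#'
#' @param plate an `mqc_plate` whose signals are already normalized (%).
#' @param conc1,conc2 dose ladders to attach; either vectors (recycled to
#'   all blocks) or a function of N returning a ladder. Defaults to
#'   [dose_ladder()].
#' @param readout_direction readout orientation for the resulting blocks.
#' @return named list of `response_block`.
#' @export
deconvolute_blocks <- function(plate, conc1 = NULL, conc2 = NULL,
                               readout_direction = "signal_decreasing") {
  w <- plate$wells[!is.na(plate$wells$block_id), ]
  if (!nrow(w)) stop("plate has no block-mapped wells")
  lapply(split(w, w$block_id), function(d) {
    n <- max(d$block_row, d$block_col)
    m <- matrix(NA_real_, n, n)
    m[cbind(d$block_row, d$block_col)] <- d$signal
    miss <- which(is.na(m), arr.ind = TRUE)
    if (nrow(miss))
      stop(sprintf("incomplete block %s: missing well at (%d,%d)",
                   d$block_id[1], miss[1, 1], miss[1, 2]))
    l1 <- if (is.function(conc1)) conc1(n) else if (is.null(conc1)) dose_ladder(n) else conc1
    l2 <- if (is.function(conc2)) conc2(n) else if (is.null(conc2)) dose_ladder(n) else conc2
    response_block(m, l1, l2, block_id = d$block_id[1],
                   readout_direction = readout_direction)
  })
}

#' Plate and layout CSV dialects
#'
#' Plate CSV header: `plate_id,well,signal`. Layout CSV header:
#' `plate_id,well,role,block_id,block_row,block_col` with role one of
#' `pos`, `neg`, `sample` (block fields empty for controls).
#'
#' @param plate_path,layout_path CSV paths.
#' @param geometry plate geometry, `c(rows, cols)`.
#' @return list of `mqc_plate`, one per plate_id.
#' @export
read_plates <- function(plate_path, layout_path, geometry = c(32, 48)) {
  p <- utils::read.csv(plate_path, stringsAsFactors = FALSE)
  if (!identical(names(p), c("plate_id", "well", "signal")))
    stop("plate CSV header mismatch")
  l <- utils::read.csv(layout_path, stringsAsFactors = FALSE,
                       colClasses = list(block_id = "character"))
  if (!identical(names(l), c("plate_id", "well", "role", "block_id",
                             "block_row", "block_col")))
    stop("layout CSV header mismatch")
  if (!all(l$role %in% c("pos", "neg", "sample")))
    stop("layout roles must be pos|neg|sample")
  m <- merge(p, l, by = c("plate_id", "well"))
  lapply(split(m, m$plate_id), function(d) {
    xy <- well_coords(d$well)
    d$block_id[d$block_id %in% c("", NA)] <- NA
    plate(d$plate_id[1], geometry,
          data.frame(row = xy$row, col = xy$col, signal = d$signal,
                     role = d$role, block_id = d$block_id,
                     block_row = d$block_row, block_col = d$block_col))
  })
}

#' @rdname read_plates
#' @param plates list of `mqc_plate` (or one plate).
#' @export
write_plates <- function(plates, plate_path, layout_path) {
  if (inherits(plates, "mqc_plate")) plates <- list(plates)
  pw <- do.call(rbind, lapply(plates, function(p)
    data.frame(plate_id = p$plate_id, well = p$wells$well,
               signal = p$wells$signal)))
  lw <- do.call(rbind, lapply(plates, function(p)
    data.frame(plate_id = p$plate_id, well = p$wells$well,
               role = p$wells$role, block_id = p$wells$block_id,
               block_row = p$wells$block_row, block_col = p$wells$block_col)))
  utils::write.csv(pw, plate_path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(lw, layout_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(plate_path, layout_path))
}
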