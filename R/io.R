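# CSV dialects for derived tables. Feature columns use dots internally
# (dmso.v, ...) but underscores on disk, per the external interface.

FEATURE_CSV_NAMES <- c("block_id", "dmso_v", "sa_min", "sa_max",
                       "sa_matrix", "moran_p", "smoothness_p", "mono_v")

#' Read and write feature tables
#'
#' On-disk header: `block_id,dmso_v,sa_min,sa_max,sa_matrix,moran_p,
#' smoothness_p,mono_v`. Numbers are written with 6 significant digits.
#'
#' @param features data.frame from [qc_features()].
#' @param path CSV file.
#' @export
write_features <- function(features, path) {
  d <- features[c("block_id", MQC_FEATURES)]
  names(d) <- FEATURE_CSV_NAMES
  d[-1] <- lapply(d[-1], signif, digits = 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), FEATURE_CSV_NAMES))
    stop("feature CSV header mismatch: expected ",
         paste(FEATURE_CSV_NAMES, collapse = ","))
  names(d) <- c("block_id", MQC_FEATURES)
  d
}

#' Write a screen report as JSON
#'
#' Full-precision JSON document with the report fields and the
#' guideline verdict.
#'
#' @param report a `screen_report`.
#' @param path output file.
#' @export
write_screen_report <- function(report, path) {
  v <- guideline_verdict(report)
  doc <- c(unclass(report),
           list(guideline = list(pass = v$pass,
                                 criteria = as.list(v$criteria),
                                 verdict = v$verdict)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a comparison table
#'
#' CSV with header `factor,side_a,side_b,m,n_plus,n_zero,n_minus,p,
#' p_adj,significant`; `p_adj` is Benjamini-Hochberg across the rows
#' and `significant` marks adjusted p < 0.05.
#'
#' @param comparisons named list of `paired_comparison` objects; names
#'   are `factor` labels formatted `"side_a vs side_b"`.
#' @param path output CSV.
#' @export
write_comparisons <- function(comparisons, path) {
  rows <- do.call(rbind, lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    sides <- strsplit(nm, " vs ", fixed = TRUE)[[1]]
    data.frame(factor = nm, side_a = sides[1],
               side_b = if (length(sides) > 1) sides[2] else "",
               m = x$m, n_plus = x$n_plus, n_zero = x$n_zero,
               n_minus = x$n_minus, p = x$p_value)
  }))
  rows$p_adj <- bh_adjust(rows$p)
  rows$significant <- rows$p_adj < 0.05
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
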