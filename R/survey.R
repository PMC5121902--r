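#' Rater survey tables
#'
#' A survey table is an items x raters grid of quality labels
#' (Good/Medium/Bad), one label per rater per block — the format of the
#' expert crowdsourcing round that the classifier's training labels come
#' from. CSV dialect: `block_id,rater,label`, complete grid required.
#'
#' @param path CSV file.
#' @return data.frame of class `survey_table`: one row per item, one
#'   column per rater, `block_id` in rownames.
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), c("block_id", "rater", "label")))
    stop("survey CSV header mismatch: expected block_id,rater,label")
  as_survey(d)
}

as_survey <- function(d) {
  if (!all(d$label %in% c("Good", "Medium", "Bad")))
    stop("labels must be Good, Medium or Bad")
  tab <- table(d$block_id, d$rater)
  if (any(tab != 1)) stop("survey grid incomplete: every rater must label every item once")
  wide <- stats::reshape(d, idvar = "block_id", timevar = "rater",
                         direction = "wide")
  rownames(wide) <- wide$block_id
  wide$block_id <- NULL
  names(wide) <- sub("^label\\.", "", names(wide))
  if (ncol(wide) < 2) stop("need at least 2 raters")
  class(wide) <- c("survey_table", "data.frame")
  wide
}

#' @rdname read_survey
#' @param survey a `survey_table`.
#' @export
write_survey <- function(survey, path) {
  long <- data.frame(
    block_id = rep(rownames(survey), times = ncol(survey)),
    rater = rep(colnames(survey), each = nrow(survey)),
    label = unlist(survey, use.names = FALSE))
  long <- long[order(long$block_id, long$rater), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

survey_counts <- function(survey, categories = c("Good", "Medium", "Bad")) {
  t(apply(survey, 1, function(v)
    table(factor(unlist(v), levels = categories))))
}

#' Consensus labels by majority vote
#'
#' Per item, the strictly most frequent label. Items where two or more
#' labels tie for the top count are ambiguous: they receive no consensus
#' and are reported separately (the training-set construction excludes
#' them).
#'
#' @param survey a `survey_table`.
#' @return list: `consensus` (named character, consensus items only),
#'   `ambiguous` (character vector of ambiguous item ids), `breakdown`
#'   (consensus label counts).
#' @export
majority_vote <- function(survey) {
  cnt <- survey_counts(survey)
  top <- apply(cnt, 1, max)
  n_top <- rowSums(cnt == top)
  amb <- rownames(survey)[n_top > 1]
  cons_idx <- n_top == 1
  consensus <- colnames(cnt)[apply(cnt[cons_idx, , drop = FALSE], 1,
                                   which.max)]
  names(consensus) <- rownames(survey)[cons_idx]
  list(consensus = consensus, ambiguous = amb,
       breakdown = table(factor(consensus,
                                levels = c("Good", "Medium", "Bad"))))
}

#' Fleiss' kappa for inter-rater agreement
#'
#' Chance-corrected agreement among r raters assigning n items to
#' categorical labels: `kappa = (P_bar - P_e) / (1 - P_e)` with the
#' usual item-wise agreement and marginal chance terms. Undefined (an
#' error) when every vote lands in one category.
#'
#' @param survey a `survey_table`, or an items x categories count matrix.
#' @return kappa (dimensionless; 1 = perfect agreement).
#' @export
fleiss_kappa <- function(survey) {
  cnt <- if (inherits(survey, "survey_table")) survey_counts(survey)
         else as.matrix(survey)
  r <- sum(cnt[1, ])
  if (any(rowSums(cnt) != r)) stop("unequal rater counts across items")
  n <- nrow(cnt)
  pj <- colSums(cnt) / (n * r)
  pe <- sum(pj^2)
  if (pe >= 1) stop("kappa undefined: all votes in a single category")
  Pi <- (rowSums(cnt^2) - r) / (r * (r - 1))
  (mean(Pi) - pe) / (1 - pe)
}

#' Generate a synthetic expert survey
#'
#' Emulates the crowdsourcing round that produced the classifier's
#' training labels: `n_good + n_medium + n_bad` items with a strict
#' majority consensus plus `n_ambiguous` items whose votes tie. Each
#' rater labels an item correctly with probability `accuracy` and
#' otherwise mostly confuses it with the adjacent grade (Good and Bad
#' are confused with Medium far more often than with each other). The
#' default accuracy of 0.75 reproduces the moderate inter-rater
#' agreement (Fleiss' kappa around 0.35) typical of expert quality
#' surveys of this kind; the defaults mirror the published survey's
#' class breakdown (78 Bad, 24 Medium, 24 Good, 7 ambiguous, 9 raters).
#'
#' This is a synthetic stand-in for the original survey, which is not
#' redistributed with the package.
#'
#' @param n_good,n_medium,n_bad consensus items per grade.
#' @param n_ambiguous items constructed to tie.
#' @param n_raters raters (default 9).
#' @param accuracy per-vote probability of the intended grade.
#' @param seed RNG seed.
#' @return a `survey_table`.
#' @export
synthetic_survey <- function(n_good = 24, n_medium = 24, n_bad = 78,
                             n_ambiguous = 7, n_raters = 9,
                             accuracy = 0.75, seed = 1) {
  set.seed(seed)
  classes <- c("Good", "Medium", "Bad")
  a <- accuracy
  conf <- list(Good = c(a, (1 - a) * 0.85, (1 - a) * 0.15),
               Medium = c((1 - a) / 2, a, (1 - a) / 2),
               Bad = c((1 - a) * 0.15, (1 - a) * 0.85, a))
  draw <- function(c) sample.int(3, n_raters, TRUE, prob = conf[[c]])
  items <- c(rep("Bad", n_bad), rep("Medium", n_medium),
             rep("Good", n_good))
  votes <- vector("list", length(items) + n_ambiguous)
  for (i in seq_along(items)) {
    c <- items[i]
    repeat {
      v <- draw(c)
      cnt <- tabulate(v, 3)
      if (sum(cnt == max(cnt)) == 1 && classes[which.max(cnt)] == c) break
    }
    votes[[i]] <- v
  }
  amb_true <- rep_len(c("Medium", "Bad", "Good"), n_ambiguous)
  for (i in seq_len(n_ambiguous)) {
    repeat {
      v <- draw(amb_true[i])
      cnt <- tabulate(v, 3)
      if (sum(cnt == max(cnt)) > 1) break
    }
    votes[[length(items) + i]] <- v
  }
  ord <- sample(seq_along(votes))   # shuffle item order
  wide <- as.data.frame(do.call(rbind, lapply(votes[ord], function(v)
    classes[v])), stringsAsFactors = FALSE)
  names(wide) <- paste0("rater", seq_len(n_raters))
  rownames(wide) <- sprintf("B%03d", seq_along(votes))
  class(wide) <- c("survey_table", "data.frame")
  wide
}
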