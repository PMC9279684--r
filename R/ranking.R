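# Rank probabilities (rankograms), best-treatment probabilities, and the
# combined efficacy-safety ranking.

#' Rank-probability table (rankogram data)
#'
#' For every stored draw the treatments are ranked by their relative event
#' log-odds against the reference (the reference itself sits at 0). With
#' `direction = "lower"` (events are harms: deaths, bleeds) the smallest
#' log-odds ranks 1 = best. Probabilities are rank frequencies over draws;
#' the resulting matrix is doubly stochastic by construction.
#'
#' @param sample an `nma_sample`, or a numeric matrix of basic-parameter
#'   draws (columns = non-reference treatments, named) which is augmented
#'   with a zero reference column named by `reference`
#' @param direction `"lower"` if a smaller event probability is better
#' @param reference reference label when `sample` is a plain matrix
#' @param outcome optional outcome label carried in the result
#' @return a `rank_table`: list with `outcome`, `direction`, `treatments`,
#'   `probs` (treatments x ranks) and `p_best`
#' @export
rank_probabilities <- function(sample, direction = c("lower", "higher"),
                               reference = "AC", outcome = NULL) {
  direction <- match.arg(direction)
  if (inherits(sample, "nma_sample")) {
    D <- .d_draw_matrix(sample)
    colnames(D) <- sub("^d_", "", colnames(D))
    outcome <- outcome %||% sample$outcome
  } else {
    D <- as.matrix(sample)
    if (ncol(D) > 0) stopifnot(!is.null(colnames(D)))
    if (!reference %in% colnames(D)) {
      D <- cbind(matrix(0, nrow(D), 1, dimnames = list(NULL, reference)), D)
    }
  }
  trts <- colnames(D)
  tn <- length(trts)
  sgn <- if (direction == "lower") 1 else -1
  probs <- matrix(0, tn, tn, dimnames = list(trts, paste0("rank", seq_len(tn))))
  if (tn == 1) {
    probs[1, 1] <- 1
  } else {
    rk <- t(apply(sgn * D, 1, rank, ties.method = "first"))
    for (t in seq_len(tn)) {
      probs[t, ] <- tabulate(rk[, t], nbins = tn) / nrow(D)
    }
  }
  structure(list(outcome = outcome, direction = direction, treatments = trts,
                 probs = probs, p_best = probs[, 1]),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("<rank_table%s> (%s event probability is better)\n",
              if (is.null(x$outcome)) "" else paste0(": ", x$outcome),
              x$direction))
  print(round(x$probs, 3))
  invisible(x)
}

#' Probability of ranking best
#'
#' @param table a `rank_table`
#' @return named numeric: per-treatment probability of rank 1
#' @export
best_probability <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  table$p_best
}

# SUCRA-style score: sum_j P(rank j) * (T - j) / (T - 1); 1 = always best
.rank_score <- function(rt) {
  tn <- length(rt$treatments)
  if (tn == 1) return(stats::setNames(1, rt$treatments))
  wts <- (tn - seq_len(tn)) / (tn - 1)
  drop(rt$probs %*% wts)
}

#' Combined efficacy-safety ranking
#'
#' The published ranking figure combines an efficacy and a safety outcome
#' without stating a rule; this package defines the combined score as the
#' mean of the two outcomes' SUCRA-style rank scores
#' (`sum_j P(rank j) * (T - j)/(T - 1)`, 1 = always best), an explicit
#' interpretation always emitted alongside the raw per-outcome tables.
#' Ties in the combined score order alphabetically.
#'
#' @param eff,saf `rank_table`s for the efficacy and safety outcome over
#'   the same treatment set
#' @return a `combined_ranking`: list with `outcomes`, `score` (per
#'   treatment, in `[0, 1]`) and `order` (best first)
#' @export
combined_ranking <- function(eff, saf) {
  stopifnot(inherits(eff, "rank_table"), inherits(saf, "rank_table"))
  if (!setequal(eff$treatments, saf$treatments)) {
    stop_trinet("treatment sets differ between the two rank tables (%s vs %s)",
                paste(eff$treatments, collapse = ","),
                paste(saf$treatments, collapse = ","),
                class = "trinet_validation_error")
  }
  s_eff <- .rank_score(eff)
  s_saf <- .rank_score(saf)[eff$treatments]
  score <- (s_eff + s_saf) / 2
  ord <- names(score)[order(-score, names(score))]
  structure(list(outcomes = c(efficacy = eff$outcome %||% NA_character_,
                              safety = saf$outcome %||% NA_character_),
                 score = score, order = ord),
            class = "combined_ranking")
}

#' @export
print.combined_ranking <- function(x, ...) {
  cat("<combined_ranking>", paste(x$order, collapse = " > "), "\n")
  print(round(x$score[x$order], 3))
  invisible(x)
}

#' Rank table as a plot-ready long data frame
#'
#' @param table a `rank_table`
#' @return data frame with `treatment`, `rank`, `probability`
#' @export
rank_long <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  tn <- length(table$treatments)
  data.frame(treatment = rep(table$treatments, tn),
             rank = rep(seq_len(tn), each = tn),
             probability = as.vector(table$probs))
}
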