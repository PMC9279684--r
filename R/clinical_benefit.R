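# Net clinical benefit of post- vs pre-thrombolysis anticoagulation:
# weighting factor x (ICH risk averted) minus the mortality excess, with a
# seeded parametric-bootstrap uncertainty interval.

#' Net clinical benefit
#'
#' `NCB = w * (ti_pre - ti_post) - (tm_post - tm_pre)`, in risk-difference
#' units. `ti_*` are short-term intracranial-hemorrhage risks and `tm_*`
#' short-term mortality risks of the pre- and post-thrombolysis
#' anticoagulation groups. The default weight 0.75 values one ICH event at
#' 75% of one death; NCB > 0 exactly when the weighted ICH risk averted by
#' post-thrombolysis anticoagulation exceeds its mortality excess.
#'
#' @param ti_pre,ti_post ICH risks (proportions in `[0, 1]`)
#' @param tm_pre,tm_post mortality risks (proportions in `[0, 1]`)
#' @param w weighting factor in `[0, 1]`
#' @return the net clinical benefit (numeric scalar)
#' @export
#' @examples
#' net_clinical_benefit(29 / 594, 0, 17 / 890, 7 / 147)
net_clinical_benefit <- function(ti_pre, ti_post, tm_pre, tm_post, w = 0.75) {
  risks <- c(ti_pre = ti_pre, ti_post = ti_post,
             tm_pre = tm_pre, tm_post = tm_post)
  if (any(!is.finite(risks)) || any(risks < 0) || any(risks > 1)) {
    stop_trinet("risks must be proportions in [0, 1]",
                class = "trinet_validation_error")
  }
  if (!is.finite(w) || w < 0 || w > 1) {
    stop_trinet("weighting factor must be in [0, 1]",
                class = "trinet_validation_error")
  }
  w * (ti_pre - ti_post) - (tm_post - tm_pre)
}

#' Net clinical benefit with parametric-bootstrap uncertainty
#'
#' The point value applies [net_clinical_benefit()] to the observed
#' proportions. Uncertainty (the source analysis reports an interval
#' without a method) is a seeded parametric bootstrap: each group's event
#' count is resampled as `Binomial(n, observed proportion)`, the NCB is
#' recomputed per replicate, and the 95% interval is the percentile
#' interval of the replicates.
#'
#' @param counts nested list of pooled counts:
#'   `list(ich = list(pre = c(events, n), post = c(events, n)),
#'         mortality = list(pre = ..., post = ...))`
#' @param w weighting factor in `[0, 1]`
#' @param reps bootstrap replicates (>= 1000)
#' @param seed integer seed; intervals are identical under the same seed
#' @return an `ncb_result`: list with `value`, `ci_low`, `ci_high`, `w`,
#'   `inputs`, `reps`, `method`
#' @export
ncb_uncertainty <- function(counts, w = 0.75, reps = 10000, seed = 1) {
  stopifnot(reps >= 1000)
  g <- function(x) {
    stopifnot(length(x) == 2, x[1] >= 0, x[2] >= 1, x[1] <= x[2])
    c(events = as.integer(x[1]), n = as.integer(x[2]))
  }
  ip <- g(counts$ich$pre);  io <- g(counts$ich$post)
  mp <- g(counts$mortality$pre); mo <- g(counts$mortality$post)
  value <- net_clinical_benefit(ip[[1]] / ip[[2]], io[[1]] / io[[2]],
                                mp[[1]] / mp[[2]], mo[[1]] / mo[[2]], w)
  set.seed(seed)
  draw <- function(x) rbinom(reps, x[2], x[1] / x[2]) / x[2]
  boot <- w * (draw(ip) - draw(io)) - (draw(mo) - draw(mp))
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(list(value = value, ci_low = ci[1], ci_high = ci[2], w = w,
                 inputs = list(ich = list(pre = ip, post = io),
                               mortality = list(pre = mp, post = mo)),
                 reps = as.integer(reps), seed = as.integer(seed),
                 method = "parametric binomial bootstrap, percentile 95% interval"),
            class = "ncb_result")
}

#' @export
print.ncb_result <- function(x, ...) {
  cat(sprintf("Net clinical benefit: %.4f (%.4f, %.4f), w = %.2f\n",
              x$value, x$ci_low, x$ci_high, x$w))
  cat(" ", x$method, "\n")
  invisible(x)
}

#' Pooled NCB inputs from arm-level data
#'
#' Derives the four (events, n) pairs from the pooled thrombolysis-arm
#' totals of the ICH and mortality outcome datasets: `pre`/`post` are the
#' pre- and post-thrombolysis anticoagulation treatment groups.
#'
#' @param arms a `trial_arms` data frame containing both outcomes
#' @param ich_outcome,mortality_outcome outcome labels
#' @param pre,post treatment labels of the two thrombolysis strategies
#' @return the `counts` structure consumed by [ncb_uncertainty()]
#' @export
ncb_inputs <- function(arms, ich_outcome = "ich",
                       mortality_outcome = "all_cause_mortality",
                       pre = "preTL", post = "postTL") {
  pools <- lapply(c(ich_outcome, mortality_outcome), function(o)
    pool_by_treatment(build_outcome_dataset(arms, o)))
  pick <- function(pool, trt) {
    row <- pool[pool$treatment == trt, ]
    if (!nrow(row)) {
      stop_trinet("treatment '%s' absent from pooled table", trt,
                  class = "trinet_validation_error")
    }
    c(row$events, row$n)
  }
  list(ich = list(pre = pick(pools[[1]], pre), post = pick(pools[[1]], post)),
       mortality = list(pre = pick(pools[[2]], pre),
                        post = pick(pools[[2]], post)))
}
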