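#' @keywords internal
"_PACKAGE"

#' @useDynLib trinet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm rbinom runif var median plogis qlogis
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in clinical
#' meta-analyses conventionally round half up. A small epsilon guards
#' against values such as 17.485 being stored as 17.48499...
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_up(c(0.125, 17.4825 * 1), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_trinet <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "trinet_error")))
}

# Largest-remainder (Hamilton) apportionment of an integer total across
# weights, with optional per-cell lower bound and cap. Ties on fractional
# part go to the earlier index; fully deterministic.
largest_remainder <- function(total, weights, min_each = 0L, cap = Inf) {
  k <- length(weights)
  stopifnot(total >= 0, k >= 1, all(weights >= 0), sum(weights) > 0)
  cap <- rep_len(cap, k)
  min_each <- rep_len(as.integer(min_each), k)
  if (sum(min_each) > total) min_each <- rep_len(0L, k)
  quota <- total * weights / sum(weights)
  out <- pmin(floor(quota), cap)
  rem <- total - sum(out)
  frac <- quota - floor(quota)
  # hand out remainder by descending fractional part, earlier index wins ties
  ord <- order(-frac, seq_len(k))
  i <- 1L
  while (rem > 0 && i <= 4L * k) {
    j <- ord[((i - 1L) %% k) + 1L]
    if (out[j] < cap[j]) {
      out[j] <- out[j] + 1L
      rem <- rem - 1L
    }
    i <- i + 1L
  }
  if (rem > 0) stop_trinet("cannot apportion %d units under caps", total,
                           class = "trinet_infeasible")
  # enforce lower bounds by pulling from the largest holders
  short <- which(out < min_each)
  for (j in short) {
    while (out[j] < min_each[j]) {
      donors <- which(out > min_each & seq_along(out) != j)
      if (!length(donors)) break
      d <- donors[which.max(out[donors])]
      out[d] <- out[d] - 1L
      out[j] <- out[j] + 1L
    }
  }
  as.integer(out)
}
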