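# Convergence (Brooks-Gelman-Rubin PSRF, trace series) and pairwise
# heterogeneity (Cochran Q, I-squared with the 25%/75% grading).

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Univariate PSRF with the Brooks-Gelman finite-sample correction,
#' computed by default on the second half of each chain:
#' with `m` chains of length `n`, within-chain variance `W` and
#' between-chain variance `B` (of chain means, times `n`),
#' `PSRF = sqrt(((n - 1)/n * W + (m + 1)/(m n) * B) / W)`.
#' Values near 1 indicate convergence.
#'
#' @param x an `nma_sample` (with `parameter`), a matrix
#'   (iterations x chains), or a list of equal-length chain vectors
#' @param parameter parameter name when `x` is an `nma_sample`
#' @param second_half use only the second half of each chain (default)
#' @param threshold pass threshold on the PSRF (default 1.05)
#' @return a `psrf_result`: list with `parameter`, `psrf`, `n_chains`,
#'   `n_draws`, `pass`
#' @export
gelman_rubin <- function(x, parameter = NULL, second_half = TRUE,
                         threshold = 1.05) {
  if (inherits(x, "nma_sample")) {
    stopifnot(!is.null(parameter))
    x <- param_draws(x, parameter)
  }
  if (is.list(x) && !is.data.frame(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2) {
    stop_trinet("PSRF requires at least 2 chains (got %d)", m,
                class = "trinet_validation_error")
  }
  if (second_half) {
    x <- x[seq(floor(nrow(x) / 2) + 1, nrow(x)), , drop = FALSE]
  }
  n <- nrow(x)
  if (n < 10) {
    stop_trinet("PSRF requires at least 10 draws per chain (got %d)", n,
                class = "trinet_validation_error")
  }
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  psrf <- if (W <= 0) 1 else sqrt(((n - 1) / n * W + (m + 1) / (m * n) * B) / W)
  structure(list(parameter = parameter %||% NA_character_, psrf = psrf,
                 n_chains = m, n_draws = n, pass = psrf <= threshold),
            class = "psrf_result")
}

#' @export
print.psrf_result <- function(x, ...) {
  cat(sprintf("PSRF%s = %.4f (%d chains x %d draws)%s\n",
              if (is.na(x$parameter)) "" else paste0("[", x$parameter, "]"),
              x$psrf, x$n_chains, x$n_draws,
              if (x$pass) "" else "  ** above threshold **"))
  invisible(x)
}

#' PSRF report for all parameters of a fit
#'
#' @param sample an `nma_sample`
#' @param threshold pass threshold (default 1.05)
#' @param include all parameters by default; restrict with a character
#'   vector of names
#' @return data frame with `parameter`, `psrf`, `pass`
#' @export
psrf_report <- function(sample, threshold = 1.05, include = NULL) {
  stopifnot(inherits(sample, "nma_sample"))
  nm <- include %||% param_names(sample)
  res <- lapply(nm, function(p)
    gelman_rubin(sample, parameter = p, threshold = threshold))
  data.frame(parameter = nm,
             psrf = vapply(res, `[[`, 0, "psrf"),
             pass = vapply(res, `[[`, TRUE, "pass"),
             row.names = NULL)
}

#' Trace series of one parameter
#'
#' Draw order and chain identity are preserved; the long format is ready
#' for CSV export and trace plotting.
#'
#' @param sample an `nma_sample`
#' @param parameter a name from [param_names()]
#' @return data frame with `chain`, `iteration`, `value`
#' @export
trace_series <- function(sample, parameter) {
  m <- param_draws(sample, parameter)
  data.frame(chain = rep(seq_len(ncol(m)), each = nrow(m)),
             iteration = rep(seq_len(nrow(m)), ncol(m)),
             value = as.vector(m))
}

#' Cochran Q and I-squared for one pairwise comparison
#'
#' Per-trial log odds ratios are pooled by inverse variance;
#' `Q = sum w_i (y_i - yhat)^2`, `I2 = max(0, (Q - df)/Q) * 100`, graded
#' mild (< 25%), moderate (25-75%) or severe (> 75%). Tables containing a
#' zero cell receive a 0.5 continuity correction on all four cells (this
#' frequentist path only; the Bayesian likelihood needs none). Either
#' 2x2 `tables` (columns `r1`, `n1`, `r2`, `n2`) or precomputed effects
#' `yi`/`sei` may be supplied.
#'
#' @param tables data frame of per-trial 2x2 counts (treatment arm 1 vs 2)
#' @param yi,sei per-trial log odds ratios and standard errors
#' @param comparison optional comparison label
#' @return a `het_result`: list with `comparison`, `k`, `q`, `df`, `i2`,
#'   `grade`
#' @export
i_squared <- function(tables = NULL, yi = NULL, sei = NULL,
                      comparison = NA_character_) {
  if (is.null(yi)) {
    stopifnot(is.data.frame(tables),
              all(c("r1", "n1", "r2", "n2") %in% names(tables)))
    cc <- with(tables, r1 == 0 | r2 == 0 | r1 == n1 | r2 == n2) * 0.5
    a <- tables$r1 + cc; b <- tables$n1 - tables$r1 + cc
    c_ <- tables$r2 + cc; d <- tables$n2 - tables$r2 + cc
    yi <- log(a * d / (b * c_))
    sei <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  }
  k <- length(yi)
  if (k < 2) {
    stop_trinet("heterogeneity requires at least 2 trials (got %d)", k,
                class = "trinet_validation_error")
  }
  w <- 1 / sei^2
  yhat <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - yhat)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  grade <- if (i2 < 25) "mild" else if (i2 <= 75) "moderate" else "severe"
  structure(list(comparison = comparison, k = k, q = q, df = df, i2 = i2,
                 grade = grade),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("I2%s = %.1f%% (%s); Q = %.2f on %d df, k = %d\n",
              if (is.na(x$comparison)) "" else paste0("[", x$comparison, "]"),
              x$i2, x$grade, x$q, x$df, x$k))
  invisible(x)
}

#' Pairwise heterogeneity report for an outcome dataset
#'
#' Builds the per-trial 2x2 tables of every comparison edge with at least
#' two trials and runs [i_squared()] on each. For edges involving the
#' reference the reference is arm 2; other edges order treatments
#' alphabetically.
#'
#' @param ds an `outcome_dataset`
#' @param reference reference treatment label
#' @return list of `het_result`, named by comparison
#' @export
heterogeneity_report <- function(ds, reference = "AC") {
  stopifnot(inherits(ds, "outcome_dataset"))
  net <- build_network(ds)
  out <- list()
  for (e in seq_len(nrow(net$edges))) {
    t1 <- net$edges$t1[e]; t2 <- net$edges$t2[e]
    if (t2 == reference || (t1 == reference && t2 != reference)) {
      # put the non-reference treatment first
      pair <- if (t1 == reference) c(t2, t1) else c(t1, t2)
    } else {
      pair <- sort(c(t1, t2))
    }
    sids <- intersect(unique(ds$rows$study_id[ds$rows$treatment == pair[1]]),
                      unique(ds$rows$study_id[ds$rows$treatment == pair[2]]))
    if (length(sids) < 2) next
    tab <- do.call(rbind, lapply(sids, function(s) {
      a1 <- ds$rows[ds$rows$study_id == s & ds$rows$treatment == pair[1], ]
      a2 <- ds$rows[ds$rows$study_id == s & ds$rows$treatment == pair[2], ]
      data.frame(r1 = a1$r, n1 = a1$n, r2 = a2$r, n2 = a2$n)
    }))
    key <- paste(pair[1], "vs", pair[2])
    out[[key]] <- i_squared(tables = tab, comparison = key)
  }
  out
}
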