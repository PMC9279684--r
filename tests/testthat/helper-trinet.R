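# shared fixtures and oracles

# desk-scale-down config for fast unit tests
quick_cfg <- function(seed = 1, chains = 2, burn = 500, iters = 1500) {
  mcmc_config(chains = chains, burn_in = burn, iterations = iters,
              thin = 1, seed = seed)
}

# one 2-arm trial in long format
toy_trial <- function(r1, n1, r2, n2, trt = c("T", "AC"), sid = "s1",
                      outcome = "y") {
  data.frame(study_id = sid, treatment = trt, outcome = outcome,
             n = c(n1, n2), events = c(r1, r2))
}

toy_dataset <- function(...) build_outcome_dataset(rbind(...), "y")

# independent Woolf log-OR oracle (0.5 continuity when any cell is zero)
woolf <- function(r1, n1, r2, n2) {
  cc <- any(c(r1, n1 - r1, r2, n2 - r2) == 0) * 0.5
  a <- r1 + cc; b <- n1 - r1 + cc; c_ <- r2 + cc; d <- n2 - r2 + cc
  list(y = log(a * d / (b * c_)), se = sqrt(1 / a + 1 / b + 1 / c_ + 1 / d))
}

# inverse-variance pooled log-OR over per-trial 2x2 rows
iv_pool <- function(tab) {
  ys <- mapply(function(r1, n1, r2, n2) woolf(r1, n1, r2, n2)$y,
               tab$r1, tab$n1, tab$r2, tab$n2)
  ses <- mapply(function(r1, n1, r2, n2) woolf(r1, n1, r2, n2)$se,
                tab$r1, tab$n1, tab$r2, tab$n2)
  w <- 1 / ses^2
  sum(w * ys) / sum(w)
}

# pooled posterior-median log-OR of the (single) non-reference treatment
fit_median_d <- function(fit) {
  median(do.call(rbind, fit$d)[, 1])
}
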