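# binomial-logit NMA: posterior correctness against frequentist oracles,
# DIC, model selection, league tables

test_that("symmetric single trial gives OR near 1", {
  ds <- toy_dataset(toy_trial(50, 100, 50, 100))
  fit <- nma_fit(ds, model_spec("fixed"), quick_cfg(seed = 2))
  re <- relative_effects(fit)
  expect_lt(abs(re$or_median - 1), 0.12)
  expect_lt(re$ci_low, 1)
  expect_gt(re$ci_high, 1)
})

test_that("single-trial posterior matches the Woolf odds ratio", {
  ds <- toy_dataset(toy_trial(10, 100, 5, 100))
  fit <- nma_fit(ds, model_spec("fixed"), mcmc_config(seed = 3))
  re <- relative_effects(fit)
  expect_lt(abs(re$or_median - (10 / 90) / (5 / 95)), 0.25)
})

test_that("posterior median matches inverse-variance pooling on homogeneous trials", {
  set.seed(10)
  arms <- generate_network(c(T1 = -0.4), tau = 0, trials_per_edge = 5,
                           n_per_arm = 200, baseline_mean = -1.4, seed = 10)
  ds <- build_outcome_dataset(arms, "event")
  tab <- do.call(rbind, lapply(unique(ds$rows$study_id), function(s) {
    sub <- ds$rows[ds$rows$study_id == s, ]
    data.frame(r1 = sub$r[sub$treatment == "T1"], n1 = sub$n[sub$treatment == "T1"],
               r2 = sub$r[sub$treatment == "AC"], n2 = sub$n[sub$treatment == "AC"])
  }))
  fit <- nma_fit(ds, model_spec("fixed"), mcmc_config(seed = 11))
  expect_lt(abs(fit_median_d(fit) - iv_pool(tab)), 0.1)
})

test_that("random-effects model recovers generator truth", {
  arms <- generate_network(c(T1 = -0.5), tau = 0.1, trials_per_edge = 20,
                           n_per_arm = 500, seed = 11)
  ds <- build_outcome_dataset(arms, "event")
  fit <- nma_fit(ds, model_spec("random"), quick_cfg(seed = 5, burn = 1000,
                                                     iters = 4000))
  expect_lt(abs(fit_median_d(fit) - (-0.5)), 0.15)
  expect_true(all(unlist(fit$tau) >= 0))
})

test_that("draw-wise consistency holds exactly and chains commute", {
  arms <- generate_network(c(A = 0.4, B = -0.3), tau = 0, trials_per_edge = 4,
                           n_per_arm = 150, seed = 6)
  ds <- build_outcome_dataset(arms, "event")
  fit <- nma_fit(ds, model_spec("fixed"), quick_cfg(seed = 6))
  re <- relative_effects(fit, pairwise = TRUE)
  # A vs B summarised from draw-wise d_A - d_B must equal the table row
  D <- do.call(rbind, fit$d)
  q <- unname(quantile(exp(D[, "d_A"] - D[, "d_B"]), c(0.5, 0.025, 0.975)))
  row <- re[re$comparison == "A vs B", ]
  expect_equal(row$or_median, q[1])
  expect_equal(c(row$ci_low, row$ci_high), q[2:3])

  # permuting chains leaves all summaries unchanged
  fit2 <- fit
  perm <- c(2, 1)
  for (f in c("d", "mu", "tau", "deviance")) {
    if (!is.null(fit2[[f]])) fit2[[f]] <- fit2[[f]][perm]
  }
  expect_equal(relative_effects(fit2, pairwise = TRUE)$or_median, re$or_median)
  expect_equal(compute_dic(fit2)$dic, compute_dic(fit)$dic)
})

test_that("random-effects posterior with tau pinned at 0 matches fixed effects", {
  ds <- toy_dataset(toy_trial(12, 80, 20, 80, sid = "a"),
                    toy_trial(9, 60, 15, 60, sid = "b"),
                    toy_trial(15, 90, 24, 90, sid = "c"))
  cfg <- quick_cfg(seed = 8, burn = 1000, iters = 4000)
  f_fix <- nma_fit(ds, model_spec("fixed"), cfg)
  # tau = 0 collapses the hierarchy exactly: identical draws, zero tau
  f_ran <- nma_fit(ds, model_spec("random", tau_fixed = 0), cfg)
  expect_equal(f_ran$d, f_fix$d)
  expect_true(all(unlist(f_ran$tau) == 0))
  # a small positive pinned tau stays close to the fixed-effects posterior
  f_small <- nma_fit(ds, model_spec("random", tau_fixed = 0.05),
                     quick_cfg(seed = 8, burn = 2000, iters = 8000))
  expect_lt(abs(fit_median_d(f_fix) - fit_median_d(f_small)), 0.1)
})

test_that("disconnected networks are rejected naming the unreachable nodes", {
  arms <- rbind(toy_trial(3, 50, 1, 50, trt = c("T", "AC"), sid = "a"),
                toy_trial(4, 50, 2, 50, trt = c("X", "Y"), sid = "b"))
  ds <- build_outcome_dataset(arms, "y")
  expect_error(nma_fit(ds, model_spec("fixed"), quick_cfg()),
               "X.*Y|unreachable", class = "trinet_network_error")
})

test_that("DIC combiner behaves at a point mass and on the conjugate toy", {
  # degenerate posterior: all draws identical -> pD = 0, DIC = Dbar
  d0 <- dic_from_deviance(rep(12.5, 100), 12.5)
  expect_equal(d0$pd, 0)
  expect_equal(d0$dic, d0$dbar)
  expect_equal(d0$dic, d0$dbar + d0$pd)

  # normal mean with known variance: pD -> 1 (one free parameter)
  set.seed(20)
  m <- 50
  y <- rnorm(m, 1, 1)
  theta <- rnorm(2e5, mean(y), sqrt(1 / m))
  dev <- vapply(theta, function(t) sum((y - t)^2), 0)
  dhat <- sum((y - mean(theta))^2)
  toy <- dic_from_deviance(dev, dhat)
  expect_lt(abs(toy$pd - 1), 0.1)

  # negative pD warns
  expect_warning(dic_from_deviance(rep(5, 50), 6), "negative")
})

test_that("random-effects pD exceeds fixed-effects pD on heterogeneous data", {
  arms <- generate_network(c(T1 = 0), tau = 0.8, trials_per_edge = 10,
                           n_per_arm = 300, baseline_mean = -1, seed = 13)
  ds <- build_outcome_dataset(arms, "event")
  cfg <- quick_cfg(seed = 13, burn = 1000, iters = 3000)
  pd_f <- compute_dic(nma_fit(ds, model_spec("fixed"), cfg))$pd
  pd_r <- compute_dic(nma_fit(ds, model_spec("random"), cfg))$pd
  expect_gt(pd_r, pd_f)
})

test_that("select_model picks the lowest DIC with fixed-model tie-breaking", {
  fx <- dic_from_deviance(rep(100, 10), 100, effects = "fixed",
                          spec = model_spec("fixed"))
  rn <- dic_from_deviance(rep(105, 10), 105, effects = "random",
                          spec = model_spec("random"))
  expect_equal(select_model(fx, rn)$effects, "fixed")
  rn2 <- dic_from_deviance(rep(95, 10), 95, effects = "random",
                           spec = model_spec("random"))
  expect_equal(select_model(fx, rn2)$effects, "random")
  tie <- dic_from_deviance(rep(100, 10), 100, effects = "random",
                           spec = model_spec("random"))
  expect_equal(select_model(fx, tie)$effects, "fixed")
})

test_that("credible intervals bracket the median and ORs stay positive", {
  fx <- build_paper_fixture("major_bleeding")
  ds <- build_outcome_dataset(fx, "major_bleeding")
  fit <- nma_fit(ds, model_spec("fixed"), quick_cfg(seed = 9))
  re <- relative_effects(fit)
  expect_true(all(re$ci_low <= re$or_median))
  expect_true(all(re$or_median <= re$ci_high))
  expect_true(all(re$ci_low > 0))
})
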