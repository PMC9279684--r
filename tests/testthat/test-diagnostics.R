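# Brooks-Gelman-Rubin PSRF, trace series, Cochran Q / I-squared

test_that("PSRF is near 1 for converged chains and large for separated ones", {
  set.seed(1)
  same <- cbind(rnorm(10000), rnorm(10000))
  r <- gelman_rubin(same)
  expect_gte(r$psrf, 0.99)
  expect_lte(r$psrf, 1.02)
  expect_true(r$pass)

  apart <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  r2 <- gelman_rubin(apart)
  expect_gt(r2$psrf, 2)
  expect_false(r2$pass)

  # duplicated chain: between-variance zero, psrf ~ 1
  x <- rnorm(2000)
  r3 <- gelman_rubin(cbind(x, x))
  expect_lt(abs(r3$psrf - 1), 0.01)
})

test_that("PSRF matches the hand formula and is affine invariant", {
  set.seed(2)
  x <- cbind(rnorm(400, 0, 1.3), rnorm(400, 0.8, 0.9), rnorm(400, -0.2, 1.1))
  # independent hand computation (second halves, Brooks-Gelman correction)
  h <- x[201:400, ]
  n <- nrow(h); m <- ncol(h)
  W <- mean(apply(h, 2, var))
  B <- n * var(colMeans(h))
  expected <- sqrt(((n - 1) / n * W + (m + 1) / (m * n) * B) / W)
  expect_equal(gelman_rubin(x)$psrf, expected)

  # affine transform of all chains jointly leaves the PSRF unchanged
  expect_equal(gelman_rubin(3.7 * x - 2)$psrf, gelman_rubin(x)$psrf)

  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains",
               class = "trinet_validation_error")
  expect_error(gelman_rubin(matrix(rnorm(8), ncol = 2), second_half = FALSE),
               "10 draws", class = "trinet_validation_error")
})

test_that("trace series preserve chain identity, order and thinning", {
  ds <- toy_dataset(toy_trial(8, 40, 4, 40))
  fit <- nma_fit(ds, model_spec("fixed"),
                 mcmc_config(chains = 3, burn_in = 200, iterations = 900,
                             thin = 3, seed = 4))
  tr <- trace_series(fit, "d_T")
  expect_equal(length(unique(tr$chain)), 3)
  expect_equal(sum(tr$chain == 1), 900 / 3)
  expect_equal(tr$value[tr$chain == 2], param_draws(fit, "d_T")[, 2])

  # CSV round trip is exact
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tr, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$value, tr$value)

  expect_error(trace_series(fit, "nope"), "available.*d_T",
               class = "trinet_validation_error")
})

test_that("I-squared matches hand computations and the grade thresholds", {
  # identical effects: no heterogeneity
  r0 <- i_squared(yi = c(0.3, 0.3), sei = c(0.1, 0.2))
  expect_equal(r0$q, 0)
  expect_equal(r0$i2, 0)
  expect_equal(r0$grade, "mild")

  # hand example: estimates 0 and 0.5, both SE 0.1 -> Q = 12.5, I2 = 92%
  r1 <- i_squared(yi = c(0, 0.5), sei = c(0.1, 0.1))
  expect_equal(r1$q, 12.5)
  expect_equal(r1$i2, 92)
  expect_equal(r1$grade, "severe")

  # invert the formula: Q = 2 df gives I2 = 50 (moderate)
  r2 <- i_squared(yi = c(0, 0.2), sei = c(0.1, 0.1))
  expect_equal(r2$i2, 50)
  expect_equal(r2$grade, "moderate")

  expect_error(i_squared(yi = 0.1, sei = 0.1), "2 trials",
               class = "trinet_validation_error")
})

test_that("I-squared is order invariant and Q doubles under duplication", {
  set.seed(3)
  yi <- rnorm(6, 0, 0.4); sei <- runif(6, 0.1, 0.3)
  a <- i_squared(yi = yi, sei = sei)
  perm <- sample(6)
  b <- i_squared(yi = yi[perm], sei = sei[perm])
  expect_equal(a$q, b$q)
  expect_equal(a$i2, b$i2)

  dup <- i_squared(yi = rep(yi, 2), sei = rep(sei, 2))
  expect_equal(dup$df, 2 * a$df + 1)
  expect_equal(dup$q, 2 * a$q)
})

test_that("zero cells get the 0.5 correction on the frequentist path", {
  tab <- data.frame(r1 = c(0, 4), n1 = c(30, 40), r2 = c(3, 5),
                    n2 = c(30, 40))
  o1 <- woolf(0, 30, 3, 30)
  o2 <- woolf(4, 40, 5, 40)
  got <- i_squared(tables = tab)
  byhand <- i_squared(yi = c(o1$y, o2$y), sei = c(o1$se, o2$se))
  expect_equal(got$q, byhand$q)
  expect_equal(got$i2, byhand$i2)
})

test_that("homogeneous fixture-sized comparisons grade mild in >= 90% of replicates", {
  fx <- build_paper_fixture("all_cause_mortality")
  ds <- build_outcome_dataset(fx, "all_cause_mortality")
  pre_ids <- unique(ds$rows$study_id[ds$rows$treatment == "preTL"])
  sizes <- do.call(rbind, lapply(pre_ids, function(s) {
    sub <- ds$rows[ds$rows$study_id == s, ]
    c(sub$n[sub$treatment == "preTL"], sub$n[sub$treatment == "AC"])
  }))
  set.seed(1)
  grades <- replicate(100, {
    p2 <- plogis(rnorm(nrow(sizes), qlogis(0.04), 0.3))
    p1 <- plogis(qlogis(p2) - 0.5)
    tab <- data.frame(r1 = rbinom(nrow(sizes), sizes[, 1], p1), n1 = sizes[, 1],
                      r2 = rbinom(nrow(sizes), sizes[, 2], p2), n2 = sizes[, 2])
    tab <- tab[tab$r1 + tab$r2 > 0, ]
    i_squared(tables = tab)$grade
  })
  expect_gte(mean(grades == "mild"), 0.90)
})

test_that("heterogeneity report covers edges with at least two trials", {
  fx <- build_paper_fixture("all_cause_mortality")
  ds <- build_outcome_dataset(fx, "all_cause_mortality")
  het <- heterogeneity_report(ds)
  expect_setequal(names(het), c("preTL vs AC", "postTL vs AC"))
  expect_equal(het[["preTL vs AC"]]$k, 11)
  expect_equal(het[["postTL vs AC"]]$k, 4)
})
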