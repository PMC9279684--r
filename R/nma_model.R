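# Binomial-logit Bayesian network meta-analysis: model/chain configuration,
# the MCMC driver around the compiled sampler, DIC, and league tables.

#' MCMC configuration
#'
#' @param chains number of chains (>= 2)
#' @param burn_in adaptation/burn-in iterations (discarded)
#' @param iterations post-burn-in iterations per chain
#' @param thin thinning interval (store every `thin`-th draw)
#' @param seed master seed; per-chain streams are derived from it
#'   deterministically
#' @return an `mcmc_config` list
#' @export
mcmc_config <- function(chains = 3, burn_in = 5000, iterations = 20000,
                        thin = 2, seed = 1) {
  stopifnot(chains >= 2, burn_in >= 0, iterations >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Named MCMC profiles
#'
#' `"desk"` is the default working profile (3 chains, 5,000 burn-in,
#' 20,000 iterations, thin 2). `"paper"` mirrors the published analysis
#' settings: 3 chains, 150,000 burn-in iterations followed by 200,000
#' iterations.
#'
#' @param profile `"desk"` or `"paper"`
#' @param seed master seed
#' @return an `mcmc_config`
#' @export
mcmc_profile <- function(profile = c("desk", "paper"), seed = 1) {
  profile <- match.arg(profile)
  switch(profile,
         desk  = mcmc_config(3, 5000, 20000, 2, seed),
         paper = mcmc_config(3, 150000, 200000, 1, seed))
}

#' Model specification
#'
#' Priors are vague on the log-odds scale: trial baselines and basic
#' parameters `Normal(0, sd^2)` with `sd = 15`, and the between-trial SD
#' `tau ~ Uniform(0, tau_upper)` (random-effects model only). `tau_fixed`
#' pins tau at a constant, which is useful for checking that the
#' random-effects posterior collapses onto the fixed-effects posterior as
#' tau -> 0.
#'
#' @param effects `"fixed"` or `"random"`
#' @param reference reference treatment label (all basic parameters are
#'   log odds ratios against it)
#' @param prior_mu_sd,prior_d_sd prior SDs for baselines and basic
#'   parameters (log-odds units)
#' @param tau_upper upper bound of the uniform prior on tau
#' @param tau_fixed optional fixed value for tau (random-effects only)
#' @return a `model_spec` list
#' @export
model_spec <- function(effects = c("random", "fixed"), reference = "AC",
                       prior_mu_sd = 15, prior_d_sd = 15, tau_upper = 5,
                       tau_fixed = NULL) {
  effects <- match.arg(effects)
  stopifnot(prior_mu_sd > 0, prior_d_sd > 0, tau_upper > 0)
  structure(list(effects = effects, reference = reference,
                 prior_mu_sd = prior_mu_sd, prior_d_sd = prior_d_sd,
                 tau_upper = tau_upper, tau_fixed = tau_fixed),
            class = "model_spec")
}

# connected component containing the reference, via the trial design graph
.check_connected <- function(rows, reference, treatments) {
  reach <- reference
  repeat {
    studies <- unique(rows$study_id[rows$treatment %in% reach])
    nxt <- unique(rows$treatment[rows$study_id %in% studies])
    if (all(nxt %in% reach)) break
    reach <- union(reach, nxt)
  }
  miss <- setdiff(treatments, reach)
  if (length(miss)) {
    stop_trinet("network disconnected from reference '%s': unreachable %s",
                reference, paste(miss, collapse = ", "),
                class = "trinet_network_error")
  }
  invisible(TRUE)
}

#' Fit the binomial-logit network meta-analysis model
#'
#' `r_ik ~ Binomial(n_ik, p_ik)` with
#' `logit(p_ik) = mu_i + delta_ik` and `delta = 0` on each trial's
#' baseline arm. Fixed effects set `delta_ik = d[t_ik] - d[t_baseline]`;
#' random effects draw `delta_ik ~ Normal(d[t_ik] - d[t_baseline], tau^2)`.
#' Chains are initialised overdispersed (basic parameters offset by
#' 0, +2, -2, ... per chain; baselines at 0.5-continuity empirical logits)
#' and sampled by adaptive random-walk Metropolis-within-Gibbs with
#' adaptation frozen after burn-in.
#'
#' @param ds an `outcome_dataset`
#' @param spec a `model_spec`
#' @param cfg an `mcmc_config`
#' @return an `nma_sample` with per-chain draws of `d`, `mu`, `tau` (random
#'   model), the per-iteration total residual deviance, and the running
#'   posterior mean of each arm probability (used for DIC)
#' @export
nma_fit <- function(ds, spec = model_spec(), cfg = mcmc_config()) {
  stopifnot(inherits(ds, "outcome_dataset"), inherits(spec, "model_spec"),
            inherits(cfg, "mcmc_config"))
  rows <- ds$rows
  if (!nrow(rows)) {
    stop_trinet("no retained rows to fit for outcome '%s'", ds$outcome,
                class = "trinet_validation_error")
  }
  treatments <- c(spec$reference,
                  sort(setdiff(unique(rows$treatment), spec$reference)))
  if (!spec$reference %in% rows$treatment) {
    stop_trinet("reference treatment '%s' absent from the dataset",
                spec$reference, class = "trinet_validation_error")
  }
  .check_connected(rows, spec$reference, treatments)
  studies <- unique(rows$study_id)
  trial_idx <- match(rows$study_id, studies) - 1L
  trt_idx <- match(rows$treatment, treatments) - 1L
  n_trt <- length(treatments)
  n_trial <- length(studies)
  random <- spec$effects == "random"
  # tau pinned at exactly 0 collapses the hierarchy analytically:
  # delta == d difference, i.e. the fixed-effects likelihood. Sampling the
  # degenerate hierarchy instead would freeze the chain (infinite prior
  # precision on delta), so the collapse is applied before sampling.
  tau_zero <- random && !is.null(spec$tau_fixed) && spec$tau_fixed == 0
  sample_random <- random && !tau_zero

  # empirical-logit baseline inits (0.5 continuity, initialisation only)
  base_arm <- vapply(seq_len(n_trial), function(i) {
    a <- which(trial_idx == i - 1L)
    a[which.min(trt_idx[a])]
  }, 0L)
  init_mu <- log((rows$r[base_arm] + 0.5) / (rows$n[base_arm] - rows$r[base_arm] + 0.5))

  offsets <- c(0, 2, -2, 4, -4, 6, -6)
  set.seed(cfg$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, cfg$chains)

  chains <- vector("list", cfg$chains)
  for (c in seq_len(cfg$chains)) {
    off <- offsets[((c - 1L) %% length(offsets)) + 1L]
    init_d <- c(0, rep(off, n_trt - 1L))
    set.seed(chain_seeds[c])
    chains[[c]] <- .nma_mcmc_chain(
      trial_idx, trt_idx, rows$r, rows$n, n_trt, n_trial, sample_random,
      spec$prior_mu_sd, spec$prior_d_sd, spec$tau_upper,
      if (is.null(spec$tau_fixed)) numeric(0) else spec$tau_fixed,
      cfg$burn_in, cfg$iterations, cfg$thin,
      init_d, init_mu, 0.5)
  }

  nstore <- chains[[1]]$n_stored
  d_names <- paste0("d_", treatments[-1])
  mu_names <- paste0("mu_", studies)
  d_list <- lapply(chains, function(ch) {
    m <- ch$d[seq_len(nstore), , drop = FALSE]; colnames(m) <- d_names; m
  })
  mu_list <- lapply(chains, function(ch) {
    m <- ch$mu[seq_len(nstore), , drop = FALSE]; colnames(m) <- mu_names; m
  })
  acc <- vapply(chains, function(ch) ch$accept_rate, 0)
  warn <- character()
  if (any(acc < 0.10 | acc > 0.70)) {
    warn <- sprintf("post-burn-in acceptance rate outside [0.10, 0.70] in chain(s) %s; adaptation may not have converged",
                    paste(which(acc < 0.10 | acc > 0.70), collapse = ", "))
    warning(warn, call. = FALSE)
  }
  pbar <- Reduce(`+`, lapply(chains, function(ch) ch$psum)) /
    (nstore * cfg$chains)

  structure(list(
    outcome = ds$outcome,
    treatments = treatments, reference = spec$reference, studies = studies,
    effects = spec$effects, spec = spec, config = cfg,
    d = d_list, mu = mu_list,
    tau = if (!random) NULL
          else if (tau_zero) lapply(seq_len(cfg$chains),
                                    function(c) rep(0, nstore))
          else lapply(chains, function(ch) ch$tau[seq_len(nstore)]),
    deviance = lapply(chains, function(ch) ch$deviance[seq_len(nstore)]),
    pbar = pbar, data = rows, accept_rate = acc, warnings = warn
  ), class = "nma_sample")
}

#' @export
print.nma_sample <- function(x, ...) {
  cat(sprintf("<nma_sample: %s, %s effects>\n", x$outcome, x$effects))
  cat(sprintf("  treatments: %s (reference %s)\n",
              paste(x$treatments, collapse = ", "), x$reference))
  cat(sprintf("  %d chains x %d stored draws\n", length(x$d), nrow(x$d[[1]])))
  invisible(x)
}

#' Available parameter names of a fitted sample
#' @param sample an `nma_sample`
#' @return character vector of parameter names
#' @export
param_names <- function(sample) {
  stopifnot(inherits(sample, "nma_sample"))
  c(colnames(sample$d[[1]]), colnames(sample$mu[[1]]),
    if (!is.null(sample$tau)) "tau", "deviance")
}

#' Per-chain draws of one parameter
#' @param sample an `nma_sample`
#' @param parameter a name from [param_names()]
#' @return matrix (stored iterations x chains), draw order preserved
#' @export
param_draws <- function(sample, parameter) {
  stopifnot(inherits(sample, "nma_sample"))
  nm <- param_names(sample)
  if (!parameter %in% nm) {
    stop_trinet("unknown parameter '%s'; available: %s", parameter,
                paste(nm, collapse = ", "), class = "trinet_validation_error")
  }
  if (parameter == "tau") {
    return(do.call(cbind, sample$tau))
  }
  if (parameter == "deviance") {
    return(do.call(cbind, sample$deviance))
  }
  src <- if (parameter %in% colnames(sample$d[[1]])) sample$d else sample$mu
  do.call(cbind, lapply(src, function(m) m[, parameter]))
}

# pooled (all-chain) draws of basic parameters, reference column included
.d_draw_matrix <- function(sample) {
  D <- do.call(rbind, sample$d)
  cbind(matrix(0, nrow(D), 1, dimnames = list(NULL, paste0("d_", sample$reference))), D)
}

#' Deviance information criterion from deviance draws
#'
#' The generic combiner: `dbar` is the posterior mean deviance, `dhat` the
#' deviance at the posterior means, `pd = dbar - dhat` the effective
#' number of parameters and `dic = dbar + pd`.
#'
#' @param deviance numeric vector (or per-chain list) of deviance draws
#' @param dhat deviance evaluated at the posterior means
#' @param effects optional model label carried through to [select_model()]
#' @param spec optional `model_spec` carried through to [select_model()]
#' @return a `dic_result`
#' @export
dic_from_deviance <- function(deviance, dhat, effects = NA_character_,
                              spec = NULL) {
  dev <- unlist(deviance, use.names = FALSE)
  dbar <- mean(dev)
  pd <- dbar - dhat
  if (is.finite(pd) && pd < 0) {
    warning(sprintf("negative effective parameter count pD = %.3f", pd),
            call. = FALSE)
  }
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dbar + pd,
                 effects = effects, spec = spec),
            class = "dic_result")
}

#' Compute the DIC of a fitted model
#'
#' Deviance is the total residual deviance of the binomial likelihood;
#' `dhat` is evaluated at the posterior means of the arm probabilities
#' `p_ik` accumulated during sampling.
#'
#' @param sample an `nma_sample`
#' @param ds the `outcome_dataset` the sample was fitted to (defaults to
#'   the data stored in the sample)
#' @return a `dic_result` with fields `dbar`, `dhat`, `pd`, `dic`
#' @export
compute_dic <- function(sample, ds = NULL) {
  stopifnot(inherits(sample, "nma_sample"))
  rows <- if (is.null(ds)) sample$data else ds$rows
  stopifnot(nrow(rows) == length(sample$pbar))
  p <- sample$pbar
  rhat <- rows$n * p
  term <- function(r, n, rhat) {
    t1 <- ifelse(r > 0, r * log(r / rhat), 0)
    t2 <- ifelse(n - r > 0, (n - r) * log((n - r) / (n - rhat)), 0)
    2 * (t1 + t2)
  }
  dhat <- sum(term(rows$r, rows$n, rhat))
  dic_from_deviance(sample$deviance, dhat, effects = sample$effects,
                    spec = sample$spec)
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("<dic_result%s> Dbar = %.2f, Dhat = %.2f, pD = %.2f, DIC = %.2f\n",
              if (is.na(x$effects)) "" else paste0(": ", x$effects),
              x$dbar, x$dhat, x$pd, x$dic))
  invisible(x)
}

#' Select the model with the lowest DIC
#'
#' Ties (and equal DICs) break toward the simpler fixed-effects model.
#'
#' @param fixed_dic,random_dic `dic_result` objects from the fixed- and
#'   random-effects fits of the same dataset
#' @return the winning `model_spec` when the inputs carry one, otherwise
#'   the winning effects label
#' @export
select_model <- function(fixed_dic, random_dic) {
  stopifnot(inherits(fixed_dic, "dic_result"), inherits(random_dic, "dic_result"))
  win <- if (random_dic$dic < fixed_dic$dic) random_dic else fixed_dic
  if (!is.null(win$spec)) win$spec else win$effects
}

#' Fit both models and select by DIC
#'
#' @param ds an `outcome_dataset`
#' @param cfg an `mcmc_config`
#' @param reference reference treatment
#' @param ... further arguments passed to [model_spec()]
#' @return list with both fits (`fixed`, `random`), both `dic` results,
#'   the `selected` label and the selected `sample`
#' @export
fit_select <- function(ds, cfg = mcmc_config(), reference = "AC", ...) {
  f_spec <- model_spec(effects = "fixed", reference = reference, ...)
  r_spec <- model_spec(effects = "random", reference = reference, ...)
  f_fit <- nma_fit(ds, f_spec, cfg)
  r_fit <- nma_fit(ds, r_spec, cfg)
  f_dic <- compute_dic(f_fit)
  r_dic <- compute_dic(r_fit)
  sel <- select_model(f_dic, r_dic)$effects
  list(fixed = f_fit, random = r_fit,
       dic = list(fixed = f_dic, random = r_dic),
       selected = sel,
       sample = if (sel == "random") r_fit else f_fit)
}

#' Odds-ratio league table
#'
#' Posterior medians and equal-tailed 95% credible intervals of
#' `OR = exp(d)` for each treatment versus the reference and, when
#' `pairwise = TRUE`, for every pair of non-reference treatments by
#' draw-wise subtraction of basic parameters (exact consistency).
#'
#' @param sample an `nma_sample`
#' @param pairwise include non-reference pairwise contrasts
#' @return a `relative_effects` data frame: `treatment`, `reference`,
#'   `comparison`, `or_median`, `ci_low`, `ci_high`
#' @export
relative_effects <- function(sample, pairwise = TRUE) {
  stopifnot(inherits(sample, "nma_sample"))
  D <- .d_draw_matrix(sample)
  trts <- sample$treatments
  rows <- list()
  summarise <- function(tr, ref, draws) {
    q <- unname(quantile(exp(draws), c(0.5, 0.025, 0.975)))
    data.frame(treatment = tr, reference = ref,
               comparison = paste(tr, "vs", ref),
               or_median = q[1], ci_low = q[2], ci_high = q[3])
  }
  for (t in trts[-1]) {
    rows[[length(rows) + 1L]] <-
      summarise(t, trts[1], D[, paste0("d_", t)])
  }
  if (pairwise && length(trts) > 2) {
    others <- trts[-1]
    for (i in seq_along(others)) for (j in seq_along(others)) {
      if (i >= j) next
      rows[[length(rows) + 1L]] <-
        summarise(others[i], others[j],
                  D[, paste0("d_", others[i])] - D[, paste0("d_", others[j])])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("relative_effects", class(out))
  out
}
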