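---
title: "Methods: models, defaults, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`trinet` re-implements, as a reusable pipeline, a Bayesian network
meta-analysis of anticoagulation timing around systemic thrombolysis for
pulmonary embolism: three treatment strategies (anticoagulation alone,
`AC`; heparin started before and continued through thrombolysis, `preTL`;
heparin started only after thrombolysis, `postTL`) connected through a
star-shaped evidence network with `AC` as the shared comparator. This
vignette records the model, every tunable that matters, the numerical
choices, and — importantly — what a green test suite does and does not
establish given that the original per-trial outcome counts were never
published.

## 1. Data model and exclusion rule

Input is arm-level, long format: one row per trial arm per outcome with
`study_id`, `treatment`, `outcome`, `n` (randomized), `events`. Counts
are persons; `0 <= events <= n` is enforced at parse time. Per outcome,
a study with zero events in **every** arm is excluded before fitting: a
double-zero trial contributes no information about an odds ratio, and
retaining it would only destabilise baseline estimates. The rule is
idempotent and logged (`excluded_studies`).

## 2. The hierarchical binomial-logit model

For arm \(k\) of trial \(i\):
\[
r_{ik} \sim \mathrm{Binomial}(n_{ik}, p_{ik}), \qquad
\operatorname{logit} p_{ik} = \mu_i + \delta_{ik},
\]
with \(\delta = 0\) on the trial's baseline arm (the arm whose treatment
is earliest in the reference-first ordering). Fixed effects:
\(\delta_{ik} = d_{t_{ik}} - d_{t_{b(i)}}\). Random effects:
\(\delta_{ik} \sim N(d_{t_{ik}} - d_{t_{b(i)}}, \tau^2)\). The basic
parameters \(d_t\) are log odds ratios versus the reference
(\(d_{\mathrm{ref}} \equiv 0\)); all pairwise contrasts are draw-wise
differences, so consistency holds exactly by construction.

Assumptions worth stating: transitivity (trial populations are
exchangeable across the two edges of the star — historically shaky here,
since the `postTL` trials are mostly early-era studies); binomial arm
counts (intention-to-treat); and, in the random-effects model, a common
heterogeneity \(\tau\) across comparisons. Multi-arm trials are accepted
by the data model and handled with independent baseline-arm deltas — the
0.5 between-arm correlation adjustment is **not** applied; every network
in scope is two-arm, so this simplification is inert but is the first
thing to revisit if multi-arm trials appear.

### Priors (defaults, units, why)

| parameter | prior | unit | rationale |
|---|---|---|---|
| \(\mu_i\) | \(N(0, 15^2)\) | log-odds | vague on any realistic risk scale |
| \(d_t\) | \(N(0, 15^2)\) | log-OR | vague; ORs from e\(^{-30}\) to e\(^{30}\) |
| \(\tau\) | \(U(0, 5)\) | log-odds SD | standard weakly-informative bound; 5 already implies implausible heterogeneity |

The source analysis is silent on priors; these are configurable in
`model_spec()`.

### Sampler

Adaptive random-walk Metropolis-within-Gibbs, one univariate normal
proposal per parameter per sweep (compiled, `src/nma_mcmc.cpp`).
Step sizes adapt per parameter toward ~35% acceptance (within the
20–50% band that is near-optimal for univariate proposals) during
burn-in only and are frozen afterwards, so the retained chain satisfies
detailed balance. Chains are initialised overdispersed: basic parameters
at offsets 0, +2, −2, … by chain; baselines at empirical logits with a
0.5 continuity term (initialisation only — the Bayesian likelihood never
continuity-corrects, binomials handle \(r = 0\) natively); \(\tau\) at
0.5. One master seed drives everything: per-chain seeds are drawn from
R's RNG seeded with it, so runs are bit-reproducible.

Chain profiles: `desk` (3 chains, 5,000 burn-in, 20,000 iterations,
thin 2) is the working default and is what the tests use; `paper`
(3 / 150,000 / 200,000) mirrors the published settings and exists for
fidelity, not necessity — the desk profile already yields PSRF ≈ 1.00
on this network.

### Degenerate case: \(\tau\) pinned at 0

`model_spec(tau_fixed = 0)` collapses the hierarchy analytically onto
the fixed-effects likelihood before sampling. Sampling the degenerate
hierarchy instead would freeze the chains (infinite prior precision on
\(\delta\) makes univariate proposals unable to move the
\(d\)–\(\delta\) ridge). The τ→0 convergence property is therefore
exact at 0 and checked approximately at `tau_fixed = 0.05`.

## 3. DIC and model selection

Deviance is the total residual deviance
\(2\sum_{ik}[r \log(r/\hat r) + (n-r)\log\{(n-r)/(n-\hat r)\}]\)
(the WinBUGS convention; it differs from −2 log-likelihood only by a
data-only constant, so \(p_D\) and DIC differences are unchanged).
\(\bar D\) averages over draws; \(\hat D\) is evaluated at the posterior
means of the arm probabilities \(p_{ik}\) accumulated during sampling;
\(p_D = \bar D - \hat D\) (a warning is raised if negative, which can
happen with strong posterior asymmetry); \(\mathrm{DIC} = \bar D + p_D\).
Selection takes the strictly lower DIC; ties go to the simpler fixed
model. The source does not report which model won per outcome, so both
fits are always exposed (`fit_select()` returns both).

## 4. Diagnostics

**PSRF** is the univariate Gelman–Rubin statistic with the
Brooks–Gelman finite-sample correction, computed on the second half of
each chain: \( \widehat{R} = \sqrt{\{(n-1)/n\,W + (m+1)/(mn)\,B\}/W} \).
Pass threshold 1.05 (configurable). Multivariate PSRF and effective
sample size are out of scope in this version.

**Heterogeneity** is pairwise per comparison edge (matching forest-plot
practice), not the network-level \(\tau\) (which the random-effects fit
reports separately): per-trial log-ORs with a 0.5 continuity correction
on all four cells of any zero-containing table, inverse-variance
pooling, \(Q = \sum w_i (y_i - \hat y)^2\),
\(I^2 = \max\{0, (Q - df)/Q\} \times 100\), graded mild (< 25%),
moderate (25–75%), severe (> 75%). The scale (log-OR) and correction are
this package's documented choices; the source states only the grading
thresholds.

## 5. Ranking rules

Per draw, treatments are ranked by relative event log-odds versus the
reference (reference at 0); for harm outcomes lower is better, and the
direction flag is configurable per outcome. Rank frequencies over draws
give a doubly stochastic treatments × ranks matrix; ties within a draw
(measure-zero in practice) break by fixed treatment order for
determinism.

The published combined efficacy–safety ranking plot does not define its
combination rule. This package **defines** the combined score as the
mean of the two outcomes' SUCRA-style scores
\(\sum_j P(\text{rank } j)\,(T-j)/(T-1)\) (1 = always best, 0 = always
worst), with alphabetical tie-breaking — an explicit interpretation,
always emitted alongside the raw per-outcome tables so users can apply
their own rule. The published single-outcome "probability best" values
(0.81 for mortality) are soft context only; our fixture-based fit gives
\(P(\text{postTL best}) \approx 0.83\), consistent but not a validation
(see §7).

## 6. Net clinical benefit

\( \mathrm{NCB} = w\,(Ti_{\mathrm{pre}} - Ti_{\mathrm{post}}) -
(Tm_{\mathrm{post}} - Tm_{\mathrm{pre}}) \), with \(Ti\) the short-term
ICH risks and \(Tm\) the short-term mortality risks, default
\(w = 0.75\) (one ICH valued at 75% of one death, following disability
literature). Applied to the pooled proportions (29/594, 0/46, 17/890,
7/147) this gives **0.00810**. The source prints 0.0174 (and elsewhere
1.74% vs 17.4‰, a tenfold notational conflict); that value is not
reproducible from the stated equation and stated inputs and is treated
as non-verifiable — the package reports what the equation yields.
Uncertainty (method unstated in the source) is a seeded parametric
bootstrap: group event counts resampled as binomials at the observed
proportions, percentile 95% interval, default 10,000 replicates.

## 7. Synthetic data: the stated world, and what green means

**Generator** (`generate_network()`): trials on each (reference, t) edge
draw \(\mu_i \sim N(\text{baseline mean}, \text{baseline SD}^2)\),
\(\delta_i \sim N(d_t, \tau^2)\), then binomial arm counts — exactly the
random-effects model's data-generating process. Defaults
(baseline mean −2 ≈ 12% risk, SD 0.4, 5 trials/edge, 100/arm) are
ordinary mid-size-trial values; recovery tests use the scenario sizes
they state (e.g. 20 trials × 500/arm, true log-OR −0.5, τ = 0.1).

**Fixture** (`build_paper_fixture()`): the published analysis printed
per-trial total sizes, the pre/post stratum membership (11/4), and
pooled per-group (events, n) for three outcomes — never per-trial event
counts. The fixture therefore reconstructs: arm sizes by
largest-remainder apportionment of the printed group sizes across
reporting trials (proportional to trial size, minimum 1/arm), and events
by largest-remainder apportionment within each group (proportional to
arm size, capped at arm size), then a deterministic repair guaranteeing
every reporting trial at least one event, since the reporting sets equal
the published "reported ≥ 1 event" counts. Recurrence and composite
outcomes have **synthetic** pooled targets (only ORs were published),
flagged `printed = FALSE` in `fixture_targets()`.

One allocation is deliberately non-proportional: pooled control-group
mortality events are split across the pre-/post-trial strata as 27/16
before within-stratum proportional allocation. Purely proportional
allocation would force every control arm to the pooled 4.14% rate,
making the post-thrombolysis odds ratio exceed 1 and contradicting the
published ranking structure (postTL best for mortality). The 16/152 ≈
10.5% control mortality assigned to the post stratum matches the
historical control mortality of those early-era trials; the split was
fixed from that reasoning once, before any acceptance measurement, and
is not a tuning knob.

Consequently: green pooled-count tests establish **exact agreement with
the published group totals**; green OR/ranking tests establish that the
pipeline behaves correctly **on a plausible reconstruction** — they do
not certify the published ORs (e.g. mortality preTL 0.490 [0.080,
2.300]), which depend on the unpublished within-trial allocation and are
therefore not acceptance targets. Parameter-recovery and coverage tests
on the generator, where truth is known, carry the inferential weight
instead.

## 8. Numerical and formatting choices

* Printed percentages: half-up rounding to 2 decimals (matching the
  published style; base `round()` would round half to even).
* Credible intervals: equal-tailed quantiles (type 7), not HPD; summary
  statistic is the posterior median, consistent with the asymmetric
  published intervals.
* Largest-remainder apportionment everywhere an integer total is split,
  ties to the earlier index — deterministic.
* Integer overflow: pooled sums are accumulated in doubles and returned
  as integers.
* Grade boundary: \(I^2 = 75\%\) grades moderate (the published cuts
  leave exactly-75 undefined; "\(>75\)" is taken literally for severe).

## 9. Known source inconsistencies (recorded, not repaired)

* Printed mortality group counts 17 + 7 + 43 = 67, but the text claims
  "64 deaths"; each group count is confirmed by its printed percentage,
  so the fixture follows the group counts and the 64-total check is left
  failing on purpose in the acceptance suite.
* Per-trial sizes tabulated for the 15 trials sum to 2,077; the results
  text enrolls 2,076 and the group totals sum to 2,076. The fixture
  follows the group totals.
* The NCB 0.0174 vs computed 0.00810 (§6); the recurrence OR
  "0.013 (0.025, 0.420)" with a point estimate below its lower bound is
  presumed a typo and used nowhere.

## 10. Limitations

* No node-splitting inconsistency assessment (the star network has no
  closed loops to test).
* No contrast-level (log-OR + SE) input; arm-level only.
* No effective-sample-size/autocorrelation reporting; no publication-bias
  tooling; no figure rendering (plot-ready tables only).
* The fixture is a reconstruction; analyses of it are demonstrations of
  the pipeline, not re-estimates of the original evidence.
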