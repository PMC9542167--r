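---
title: "Estimands and estimators for 2x2 factorial trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimands and estimators for 2x2 factorial trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(festimands)
```

## The problem

A 2x2 factorial trial randomizes each participant twice: to treatment A or
not, and to treatment B or not, yielding four cells — neither, A alone, B
alone, both.  The design is attractive because "all A vs all no-A" reuses
every participant, but it makes *the effect of treatment A* ambiguous: a
participant's potential outcome under A depends on whether they also receive
B.  Writing $Y^{z_A, z_B}$ for the potential outcome under joint assignment
$(z_A, z_B)$, four distinct treatment-A estimands must be distinguished:

| Target | Contrast | Question |
|---|---|---|
| `A_GIVEN_NO_B` | $E[Y^{1,0}] - E[Y^{0,0}]$ | effect of A if no one received B |
| `A_GIVEN_B` | $E[Y^{1,1}] - E[Y^{0,1}]$ | effect of A if everyone received B |
| `A_USUAL_PRACTICE` | $E[Y^{1,Z_B^{UP}}] - E[Y^{0,Z_B^{UP}}]$ | effect of A with B given as in routine care |
| `A_PLUS_B` | $E[Y^{1,1}] - E[Y^{0,0}]$ | effect of the A+B combination vs neither |

(the differences above generalize to risk ratios and odds ratios; the
package supports `mean_difference`, `risk_difference`, `risk_ratio` and
`odds_ratio`).  The usual-practice estimand depends on $\pi$, the proportion
of patients who would receive B in practice; `festimands` treats $\pi$ as a
fixed, user-supplied constant with no sampling variance.

## Noncollapsibility and why the factorial model adjusts for B

For collapsible measures (mean difference, risk difference, risk ratio) a
population-averaged (marginal) effect is the allocation-weighted mix of the
stratum effects.  The odds ratio is not collapsible: with cell event
probabilities (50%, 33.3%, 9.1%, 4.8%) the OR for A is 0.50 in both strata
of B, yet the marginal OR in a population where half receive B is 0.56 —
without any confounding.  `cell_math` computes these quantities exactly:

```{r noncollapsible}
cells <- cell_params(0.50, 0.333, 0.091, 0.048)
conditional_effect(cells, stratum_b = 0, measure = "odds_ratio")
conditional_effect(cells, stratum_b = 1, measure = "odds_ratio")
marginal_effect(cells, pi_b = 0.5, measure = "odds_ratio")
```

This is why the package's factorial estimator always uses the *adjusted*
model `logit P(Y=1) = alpha + beta_a Z_A + beta_b Z_B`: omitting `Z_B`
estimates a marginal OR whose value depends on the trial's allocation ratio
and matches none of the four estimands.  The unadjusted model is exported
(`fit_model(..., "factorial_unadjusted")`) purely so the bias can be
demonstrated; it is never routed to an estimand.

Interaction is scale-specific.  `interaction_on_scale()` works on the
measure's link scale — identity for mean/risk differences, log for the risk
ratio, log-odds for the OR — so that "no interaction" coincides with a zero
`beta_int` coefficient in the interaction model.  The table above has zero
interaction on the log-odds scale but a risk-difference interaction of
0.124.

## Estimators

Two estimation strategies are implemented, mirroring the standard
at-the-margins vs inside-the-table distinction:

* **Factorial** (`strategy = "factorial"`): `beta_a` from the adjusted
  model (or `beta_a + beta_b` for the combination estimand).  Efficient,
  but unbiased only under no interaction; for the OR it targets the
  conditional effect.
* **Multiarm** (`strategy = "multiarm"`): the four cells as separate arms,
  `g(E[Y]) = alpha + beta_a0 Z_A0 + beta_0b Z_0B + beta_ab Z_AB`; the
  estimators `beta_a0`, `beta_ab - beta_0b` and `beta_ab` are unbiased with
  no interaction assumption, at the price of using only half the data per
  contrast.  The usual-practice estimand uses the $\pi$-weighted
  combination `(1 - pi) beta_a0 + pi (beta_ab - beta_0b)`
  (`weighted_usual_practice()`), which additionally assumes that B-receipt
  in practice does not depend on A and that the randomized-B stratum
  effects transfer to usual-practice assignment.

The interaction model is an exact reparameterization of the multiarm model
(`beta_ab = beta_a + beta_b + beta_int`); the test suite asserts this to
1e-6 on the link scale across random datasets, including the covariance
mapping.

One caveat the package surfaces rather than hides: for the *marginal*
usual-practice odds ratio no unbiased estimator exists under either
strategy, because of noncollapsibility.  Estimates for that combination
carry an explanatory `note`; a g-computation extension would be needed and
is out of scope.

### Fitting machinery and inference

The analysis models are ordinary GLM/least-squares fits, chosen per
measure:

* `odds_ratio`: logistic regression, IRLS with tolerance 1e-8, at most 100
  iterations; coefficients beyond 15 on the link scale are reported as
  likely complete separation rather than returned.
* `risk_ratio`: log-link binomial, with an explicit error on
  non-convergence (log-binomial fits can fail near the risk boundary).
* `risk_difference`: identity-link least squares on the 0/1 outcome with
  HC0 sandwich covariance (the residual variance of a linear probability
  model is heteroskedastic by construction), normal reference.
* `mean_difference`: least squares, model-based covariance, t reference
  with residual degrees of freedom.

All contrasts go through `linear_combination()`: estimate $w^\top\hat\beta$,
variance $w^\top V w$, Wald interval and two-sided p-value, with
natural-scale results obtained by exponentiating the link-scale interval
(so the natural CI is always the monotone transform of the link CI).
Exact-fit degenerate data (zero residual noise) is given an exactly zero
covariance rather than a rounding-error one, so noiseless fixtures report
`p = 1` for null contrasts.  No multiplicity adjustment is made across the
A and B questions: the two-trials-in-one framing treats them as separate
hypotheses.  Baseline-covariate adjustment is out of scope; the model
formulas are fixed, which also removes factor-releveling mistakes (treatment
coding is hard-wired to 0/1).

## The four-step framework

`run_framework()` executes the recommended analysis sequence: declare the
estimands (exactly one primary, with free-text intercurrent-event strategy
labels recorded verbatim); estimate each with the adjusted factorial model
as primary analysis; report the interaction with CI, p-value and a
CI-spread diagnostic (ratio of the natural-scale CI limits for ratio
measures — a wide spread means the interaction is too imprecisely estimated
to rule much out); and re-estimate with the multiarm estimator as
sensitivity analysis.

The concordance classification is this package's own convention, since
"broad agreement" is not a formal statistic: `consistent` when each point
estimate lies inside the other analysis's CI, `discordant` when the point
estimates fall on opposite sides of the null, `indeterminate` otherwise.
The rule is symmetric in the two analyses and is applied on the link scale.
It is a reporting aid, not a test; a discordant label flags sensitivity to
the no-interaction assumption rather than proving an interaction.

The discouraged alternative — pre-testing the interaction and switching
estimator on significance — is implemented as
`two_stage_estimator()` strictly as a negative control.  Its coverage
degrades under moderate interactions (see below); it should not be used for
inference.

## The simulator and what it does (and does not) emulate

`simulate_factorial()` draws, per participant, independent Bernoulli
assignments ($P(A) =$ `alloc_a`, $P(B) =$ `alloc_b`, defaults 0.5) and then
the outcome from the assigned cell — Bernoulli($p_{ab}$) for binary,
Normal($\mu_{ab}, \sigma$) for continuous outcomes.  Independent Bernoulli
randomization was chosen over permuted blocks because it makes the oracle
targets exact and is asymptotically equivalent for these estimators.

`simulate_usual_practice()` instead assigns B with probability
`pi_b_given_a0` / `pi_b_given_a1` depending on the realized A arm; unequal
values encode B-receipt depending on A, in which case the conditional
usual-practice estimand is marked undefined in the truth map (it is only
well defined when the stratum effects coincide on the link scale, checked
to 1e-8).

`apply_intercurrent_events()` models treatment discontinuation as an
outcome-distribution shift: a per-cell discontinuation probability, and a
shift of the cell parameter (binary probabilities clipped to [0.01, 0.99])
for discontinued participants.  Labels stay as-randomized, so downstream
analyses implement a treatment-policy strategy.  This deliberately minimal
mechanism suffices to show numerically how a treatment-policy estimate
absorbs the intercurrent event; estimation under hypothetical, composite,
while-on-treatment or principal-stratum strategies is not implemented.
The simulator also does not model death/censoring, rescue medication, or
dose-level non-adherence — so passing tests say nothing about those
features of real trials, nor about covariate imbalance, since no baseline
covariates are generated.

Seeding: every config carries a mandatory seed; replicate $r$ of a study
uses `base_seed + r`; `apply_intercurrent_events()` uses its own stream
derived from the config seed.  Simulation never touches the caller's global
RNG state.

## Monte-Carlo evaluation

`run_simulation_study()` aggregates bias, empirical SE, mean model SE, CI
coverage and the interaction test's rejection rate against the closed-form
oracles, on the link scale (where the estimators are asymptotically
normal).  Conventions, fixed once: 3x-standard-error Monte-Carlo bands for
pass/fail judgements; replicates with failed fits are excluded and counted,
with a hard error beyond 5%; coverage comparisons use an epsilon of
1e-8 so that zero-width intervals from noiseless fixtures are judged by
value, not rounding error.

Default study sizes used by the package's own checks — 500 replicates of
trials with 2,000 participants (1,000 for the two-stage study's moderate
interaction, run at 1,000 replicates), and a single 200,000-participant
trial for the adjusted-vs-unadjusted contrast — were chosen so each check's
Monte-Carlo error is comfortably below the effect it measures (for example,
a log-OR bias of about 0.49 under an interaction of 1.5, against an MC
error near 0.006).

Representative results, recomputed by `scripts/acceptance.R` on every run:
the factorial estimator is unbiased under no interaction but biased by
roughly the interaction-weighted mixture under a log-OR interaction of 1.5,
while the multiarm estimator stays unbiased with nominal coverage in both
scenarios; the weighted usual-practice estimator recovers its cohort oracle
under independent B-receipt and is biased when receipt depends on A; and
the two-stage procedure's coverage falls well below both nominal and the
multiarm strategy's under a moderate (log-OR 0.7) interaction.

## Numerical choices and edge cases

* Link scales are fixed per measure (identity / log / logit) so "no
  interaction" always means a zero coefficient in the interaction model.
* Boundary probabilities (0 or 1) are rejected in `cell_params` rather than
  continuity-corrected: the closed-form oracle must be exact.  Continuity
  corrections belong, if anywhere, in count-based descriptive summaries.
* Comparisons against two-decimal printed tables are made at two decimals.
* Missing outcomes are handled by complete-case exclusion with a logged
  count at CSV read time; the estimand machinery itself assumes complete
  data.
* The conditional usual-practice oracle returns an explicit
  `estimand_undefined` error condition, never a silent number.

## Known limitations

Two-level factors only (no 2x2x2 designs), no baseline covariates, no
survival outcomes, no Bayesian or GEE machinery, no multiplicity
adjustment, and no marginal-OR estimator for the usual-practice estimand.
The framework's concordance rule is a convention; with very wide multiarm
CIs it will often read "consistent" simply because the sensitivity analysis
is uninformative — the interaction CI-spread diagnostic is reported
precisely to make that visible.
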