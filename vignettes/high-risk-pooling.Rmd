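---
title: "High-risk pooling under prospective risk equalization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-risk pooling under prospective risk equalization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hrpsim` simulates a payment system in which a prospective risk-equalization
model is supplemented by a high-risk pool whose members are identified from
health-survey information. This vignette explains the model and procedure,
the synthetic data generator and what it does and does not emulate, the
tunable parameters, numerical choices, and the design decisions that were
genuinely open.

## The payment system

Every person carries categorical risk-adjuster classes. The regulator pays
insurers the spending predicted by an OLS regression of annual spending on
the adjuster-class dummies (one family of dummies per adjuster, intercept
included). With an intercept, residuals are mean-zero over the estimation
population — the model is zero-sum: any group's loss is the complement
group's profit.

Residual spending `e_i = y_i − ŷ_i` is the insurer's per-person profit (when
negative) or loss (when positive) under pure risk equalization. Survey
indicators — self-reported chronic conditions and general health — predict
`e_i` because they carry health information the adjusters miss. The
simulated insurer exploits this by:

1. training a predictor of `e_i` on survey indicators only (70% of
   responders), scoring the remaining 30% (the evaluated sample);
2. assigning the top X% of predicted residual spending to the pool,
   X ∈ {1, …, 5};
3. receiving, per member, `s · max(b_i − τ, 0)` where the basis `b_i` is the
   member's realised residual spending (default) or actual spending, and
   `s` is the compensated share (default 1);
4. financing the total compensation through a retrospective flat-rate
   contribution subtracted from the payment of every person outside the
   pool, so the budget balances exactly within the evaluated sample.

The threshold τ is solved, separately per pool size, so that the pool's
mean post-compensation residual is zero. With basis = residual and `s` = 1
this makes total compensation equal the sum of the members' residuals.

### Threshold solving

The retained mean `f(τ) = mean(e_i − s·max(b_i − τ, 0))` is piecewise
linear and non-decreasing in τ, strictly increasing wherever some `b_i`
exceeds τ. We solve exactly on the sorted breakpoints rather than by
bisection: for each segment the linear root is computed and accepted if it
lies in the segment. When the members' mean residual is exactly zero the
root set is `[max(b), ∞)` and the smallest root `max(b)` is returned; a
negative mean residual is infeasible (compensation is never negative, so no
threshold can raise the pool mean to zero) and raises an error. The solver
tolerance (default 1e-6 euro) only enters the feasibility test; the root
itself is exact up to floating point.

### Incentive metrics

*Selection incentives.* For a subgroup g of survey responders, the mean
result is the raking-weighted mean per-person profit (revenue − spending;
positive = overcompensation), with the design-based weighted standard error
`sqrt(Σ w²(x−x̄)²)/Σw` and a two-sided one-sample t-test at 5% (a pragmatic
choice of test; only the 5% flag is used downstream). Group sets are aggregated by the weighted mean
absolute result, `WMAR = Σ N_g |ē_g| / Σ N_g`, over four sets: the
no-chronic group plus the four "ever" conditions; all subgroups; yes/no
chronic; and general health.

*Cost-control incentives.* The power reduction is simulated by inflating
spending 10% while holding pool membership, τ and the flat contribution
fixed, recomputing compensations, and dividing the total revenue change by
the total spending change. Holding financing fixed reads "ceteris paribus"
from a single insurer's perspective: one insurer's cost change does not
move the market-wide contribution. A `recompute_financing = TRUE` mode
instead recomputes the contribution, which by construction nets the
aggregate revenue change to zero — useful as an accounting check, not as an
insurer-level incentive measure. Whose spending is shocked is also
configurable (`shock_scope`, default everyone); shocking only pool members
changes the denominator, not the numerator. Without prior-year-spending
adjusters the no-HRP baseline is fully prospective, so power reduction
relative to that baseline is reported directly.

## The synthetic population

No suitable person-level claims/survey linkage is public, so the generator
builds one with the statistical structure the analysis needs:

* **Adjusters.** Age×sex (10 classes), region (4), a yes/no morbidity flag
  (2); class effects are additive euros on conditional mean spending, so
  the OLS payment model is correctly specified for the adjuster part.
* **Spending.** Zero-inflated lognormal: an any-use gate
  (P(use) = 1 − `p_zero`, default 0.8) times a lognormal with mean equal to
  the summed class effects (sdlog 1.1), plus a latent severity component
  `h·exp(S − 1/2)` with `S ~ N(0,1)` inside the gate. Decedents
  (independent Bernoulli, 1%) have spending multiplied by 4, making the
  mortality proxy informative as a raking margin. Defaults give a mean of
  roughly 3,000 euros with ~20% zeros and a heavy right tail.
* **Hidden severity.** `h` (`hidden_severity_sd`, default 1,000 euros) is
  the euro-scale spread of what the adjusters miss. The expected residual
  under a correctly specified adjuster-only model is available in closed
  form, `p_use·k̄·h·(exp(S−1/2) − 1)` plus the designed-flag term, and is
  stored per person as `true_group_effect`; with `h = 0` it vanishes and
  survey indicators carry no residual signal — the null configuration used
  by the control tests.
* **Survey.** Condition indicators (ten 12-month conditions, prevalences
  3–14%, plus ever diabetes/stroke/heart attack/cancer) load on `S` on the
  logit scale; some also load on the morbidity adjuster, so conditions like
  diabetes are already partly compensated — reproducing the pattern that
  pooling helps some condition groups much more than others. General health
  "fair/poor" (~25% of responders) loads on `S` as well. Response among
  invitees has logit `1.4 − 0.4·S`: sicker people respond less, so the raw
  survey is selectively healthy and raking genuinely matters.
* **Designed undercompensation.** An independent flag with prevalence
  q = 0.2 adds `δ/(1−q)` euros to spending, giving the flagged group an
  expected residual of exactly δ (`group_undercompensation`) under the
  adjuster model — the target for parameter-recovery tests (δ = 500 in the
  validation runs, 0 by default).

Condition prevalences and loadings were calibrated once so that the
any-chronic group is ~60–65% of responders with a clearly negative,
statistically significant baseline loss and the healthy complement a
positive profit, matching the descriptive premise of the setting being
emulated; they are fixed defaults, not fitting targets.

What the generator does **not** emulate: the joint dependence structure of
real condition indicators beyond a single severity factor (conditions are
independent given `S` and the morbidity class), real adjuster coefficient
magnitudes, multi-year spending dynamics, and age truncation of the survey
frame. Passing tests therefore show that the *mechanics* — threshold
solving, budget balance, raking, the selection/cost-control trade-off
direction — are correct, not that euro magnitudes transfer to any real
system.

## Raking

Survey responders are reweighted by iterative proportional fitting to
population margins: every adjuster family, 18 population spending-quantile
bins, and the mortality proxy. Updates cycle in the order the margins are
listed (deterministic; the IPF limit does not depend on the order), weights
are renormalised to the population total each cycle, and convergence
requires the worst relative margin error below 1e-6 (default) within 500
iterations. Ties in the spending distribution (the zero mass) collapse
duplicate quantile cut-points; the realised bin count is reported. No
weight trimming is applied by default. With heavy ties 18 requested bins
typically become ~15; one spending column is binned (which year's spending
to average was left open by the source setting; the single current-year
column is the package's choice).

## Prediction

Features are the survey indicators only — conditions, ever-conditions, the
designed flag and the general-health dummy — never the adjusters, whose
information is already orthogonalised by the payment model. The stepwise
learner is forward selection by AIC from the intercept; the forest is
`ranger` with 100 trees and minimum node size 100, `num.threads = 1` and a
fixed seed so runs are bit-reproducible. Remaining forest hyperparameters
follow the library defaults and are recorded in the run manifest.
`top_fraction()` takes the `ceiling(f·n)` highest predictions, breaking
ties by ascending person id, which makes selections nested across pool
sizes.

## Problem sizes and numerical choices

Validation and acceptance runs use a population of 200,000 with a 30%
survey invitation (~48k responders, ~14k test persons), large enough that
the top-1% pool holds ~140 members and directional assertions are stable;
oracle-equivalence checks run on instances of at most 1,000 evaluated
persons where brute-force loops are feasible. Monetary identities (budget
balance, profit conservation) hold to floating-point accuracy (~1e-9
relative); the pool's mean retained residual is checked at 1e-6 euro.
Statistical assertions use 3 Monte-Carlo-standard-error bands; monotone
paths across pool sizes allow a per-step slack of half a standard error,
since subgroup means at adjacent pool sizes differ by small amounts
relative to sampling noise.

## Known limitations

* Euro magnitudes are properties of the synthetic configuration; only
  signs, orderings and relative reductions are meaningful.
* The threshold is solved on the evaluated sample itself (whether the
  reference procedure solved it on training data was not stated); an
  insurer solving τ ex-ante on training data would face small budget
  imbalances that this design removes by construction.
* Residuals come from a model estimated on the full current population,
  including the evaluated persons; a prior-year model would add estimation
  drift not modelled here.
* The weighted t-test treats raking weights as fixed; no
  replication-based variance estimation is attempted.
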