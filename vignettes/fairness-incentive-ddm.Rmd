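---
title: "Modelling incentivised fairness decisions with fairddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling incentivised fairness decisions with fairddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairddm)
```

## The paradigm the generator emulates

`fairddm` targets a four-group third-party fairness paradigm. Participants
first observe an allocator making mostly unfair splits (the observation
phase: 20 trials, 16 of them self-favouring, balanced 8:2 within each of
two distribution pairings). They then act as allocators themselves for 240
experimental decisions — 120 towards the fairness partner (the observed
allocator in the punishment groups, the observed receiver in the
compensation groups) and 120 towards an uninvolved baseline partner — plus
6 control trials and 12 practice trials, 278 trials in total.

Each decision offers two splits of a 500–700 point pot (steps of 10): an
*unfair* (~70:30 self:other), *equal* (~50:50) or *hyperfair* (~30:70)
option, always pairing an equal split with one of the two extremes so that
favour-self versus favour-other is never confounded with equal versus
unequal. Shares are jittered uniformly by ±5 *percentage points* around
the target ratio. We chose the percentage-point reading of the jitter over
a multiplicative ±5% because only the former covers published example
splits such as 192/680 ≈ 28.2%. The two options in a trial draw their pot
sizes independently, consistent with example trials whose options come
from different pots. Control trials present a pair in which one option is
weakly better *for both players* (constructed as `(x, y)` versus
`(x − δ, y − δ)` with δ ≥ 50), so choosing the dominated option signals
careless responding.

A trial-wise incentive of 0–500 points (6 levels × 2 pairings × 10
repetitions per partner) rewards the group's incentivised decision type:
favour-self in the aligned-punishment and conflict-compensation groups,
favour-other in the conflict-punishment and aligned-compensation groups.
The payout rule pays `points_self + incentive` when the chosen decision
type matches the incentivised type and `points_self` otherwise, at
0.005 €/point, plus a 3 € show-up fee. The printed overall payout range of
the original task description is arithmetically inconsistent with its own
per-trial minimum, so the package implements only the explicit equation
and asserts nothing about the range.

Responses are recorded as fairness **congruence**: 1 for favour-self in
the punishment domain and favour-other in the compensation domain, 0
otherwise. The same group-level code is applied to baseline-partner
trials; a partner-specific recoding would be equally defensible but the
group-level reading keeps one response variable per participant.

### What the generator does *not* emulate

Simulated participants are exchangeable given their group and parameters:
there is no learning or fatigue across trials, no sequential dependence,
no response-key or position bias, and the trait scores are draws from a
Gaussian copula whose scale locations merely mimic the named instruments
(trait anger, altruism, justice sensitivity) — they are not validated
psychometrics. Passing tests therefore demonstrate that the *analysis
chain* is correct and well calibrated for data of this structure, not that
real participants behave like the generator.

## The diffusion kernel

Choices and response times follow a Wiener diffusion with unit diffusion
coefficient (a pure scale convention), drift `v` signed towards the
fairness-congruent upper boundary (stimulus coding), boundary separation
`a`, relative start point `z` stored as a fraction of `a`, and a single
non-decision time `t0`. No inter-trial variability parameters are
included: the model space under study does not use them.

The first-passage density is evaluated from the classic small-time and
large-time series expansions. The number of terms for each expansion comes
from the standard truncation error bound at tolerance 10⁻⁷, and whichever
expansion needs fewer terms is used; the two agree to better than 10⁻⁶
across their overlap region (a tested property). The analytic absorption
probability `(1 − e^{−2vza}) / (1 − e^{−2va})` (→ `z` as `v` → 0) serves
as an independent oracle: the density's mass on each boundary must match
it to 10⁻⁴.

The simulator is Euler–Maruyama with a Brownian-bridge within-step
crossing correction, making the discretisation bias O(dt) instead of
O(√dt); at the default `dt = 1e-3` the Kolmogorov–Smirnov distance between
10⁵ simulated first passages and the analytic law is below 0.01. Simulated
task responses slower than the 4 s deadline are redrawn, mirroring the
task's repeat loop for missed trials; the likelihood deliberately ignores
this truncation, as is standard — the truncated mass is negligible for
realistic parameters (well under 1% at the default generative values) but
this is a documented approximation, not an exact treatment.

## Hierarchical estimation

Subject-level `v`, `a`, logit-`z` and `t0` are drawn from group-level
normal distributions. Condition effects enter the group-level *means*: for
each model, the mean of `v` (or of logit-`z`) is estimated per cell of the
crossed condition factors. The two-factor models V2 and Z2 therefore carry
four cell means rather than two additive offsets — the domain-difference
hypothesis below is a double difference that is identically zero under a
purely additive parameterisation, so cell means are the only
parameterisation under which that test is informative. The logistic link
on `z` guarantees that no condition or incentive effect can push a start
point outside (0, 1). The exploratory incentive models (`ZI_*`) are fitted
per experimental group and regress logit-`z` on the trial-wise incentive
level coded 0–5.

Priors are weakly informative, following common hierarchical-DDM practice:
group means Normal(0, 2) for `v`, Normal(1.5, 0.75) for `a`, Normal(0, 1)
for logit-`z` (i.e. `z` centred on 0.5), Normal(0.4, 0.2) truncated
positive for `t0`; all group scales Half-Normal(0.5); the incentive weight
Normal(0, 1). The sampler is Metropolis-within-Gibbs: random-walk updates
for subject-level parameters (proposal scales adapted towards a 0.44
acceptance rate during burn-in), conjugate draws for group means, log-scale
random-walk updates for group scales. Chains are initialised from crude
per-subject moments — `t0` safely below each subject's fastest response,
`v` from the empirical choice fraction via the absorption identity — and
jittered per chain. Convergence is monitored by split-R̂ with the gate
R̂ < 1.01; a fit that misses the gate is returned *flagged with a
warning*, never silently. A Geweke score is available as a secondary
check.

DIC conditions on the subject-level parameters (lowest-level focus, the
convention of the reference hierarchical-DDM software): the deviance trace
is −2 log-likelihood at the current subject parameters, `pD = D̄ −
D(θ̄)` with `θ̄` the posterior mean of the subject parameters on the
sampling scale, and `DIC = D̄ + pD` — an identity that holds exactly by
construction and is asserted in the tests.

## Model selection and hypothesis tests

Lower DIC is better. The selection rule resolves an ambiguity in common
verbal statements of the 10-point convention in favour of the only
self-consistent reading: a more complex model is selected outright when
its DIC undercuts every competitor by at least 10; all models strictly
within 10 points of the minimum form a model-averaging set with weights
∝ exp(−ΔDIC/2). A member model in which the parameter of interest does not
vary contributes its implied null effect (exact zeros) to the pooled
trace.

Directional hypotheses are posterior exceedance probabilities on paired
draws at the 95% threshold: H4 — `P(v_aligned > v_conflict)` with a
drift-rate model in the winning set; H5 — the same for `z` with a
start-point model; H6 — the double difference (aligned − conflict in
punishment) − (aligned − conflict in compensation), in either direction,
with a two-factor model in the winning set. A hypothesis whose parameter
is absent from every winning model is reported *not evaluable* rather than
false.

## Behavioural mixed models

All generalized linear mixed models are fitted with `lme4::glmer`
(Laplace approximation; `nAGQ = 0` available where speed matters more than
the last decimal). Quality control excludes a participant entirely for
failing ≥ 2 of the 6 control trials or for a mean response time below
0.5 s, then drops practice and control trials. The confirmatory model is
`response ~ conflict_degree * fairness_domain + conflict_degree *
incentive + (1 | participant)` on the fairness-partner trials; a full
120-participant synthetic study yields exactly 14 400 observations.
Incentive level enters as points/100 (0–5), so coefficients are per 100
points — a numerical-conditioning choice, documented rather than asserted
against any published coefficient table. The manipulation-check model
family puts a random slope over the distribution pairing; the generated
design has exactly two pairings (unfair-vs-equal, hyperfair-vs-equal), so
the four-level slope sometimes described for such designs reduces to a
two-level factor here, and singular random-slope fits are automatically
refitted with an intercept-only structure and flagged. Trait correlations
are Pearson by default (Spearman available) with a fivefold Bonferroni
correction — five scales per group.

## Power analysis and its sensitivity

`run_power()` simulates whole studies from the logistic generative model —
four groups of 30, 120 fairness-partner trials each, baseline favour-other
probabilities 0.65 (compensation) and 0.45 (punishment), logit-scale
incentive weight 0.25 per coded level in the conflict-punishment group and
0.15 elsewhere, signed towards the group's incentivised option, subject
intercept SD σ_u = 1 — and fits the confirmatory model to each. Power per
effect is the significant fraction with a Clopper–Pearson interval;
non-converging fits are dropped and counted.

Two design choices deserve emphasis because published descriptions of such
simulations typically omit them: the incentive coding and σ_u. The
conflict × incentive interaction is within-subject and its power is
essentially insensitive to σ_u (it is ≈ 100% under the default
configuration). The fairness-domain × conflict interaction, in contrast,
is a pure between-subject contrast whose only source under this generative
model is the indirect 0.25-versus-0.15 weight difference — roughly a
0.3–0.5 logit shift against a between-subject standard error of about
0.38 at σ_u = 1, giving power in the 10–30% range. That standard error
scales with σ_u: near σ_u ≈ 0–0.3 the same contrast reaches the 90%+
range. We keep σ_u = 1 as the default because a unit-scale subject
intercept is the realistic magnitude for binary social decisions, and we
treat the resulting low between-subject power as a property of the
configuration, not a defect of the estimator — the type-I calibration
tests show the test itself is accurate.

## Problem sizes and numerical defaults

The package defaults are 4 chains × 5000 draws after 2000 burn-in for
MCMC and 100 simulations for power. The test-suite checks use smaller
problems chosen to keep each property informative at desk scale: 2 chains
of a few hundred draws, 4–15 subjects per group with 60–120 trials for
recovery and model-recovery checks, 3 replicates for the DIC recovery
matrix, and 40–120 simulated studies for the calibration checks. Seeds are
fixed throughout; `derive_seed()` folds a stage name into the master seed
(always below 2³¹) so that every pipeline stage is independently
reproducible.

## Known limitations

* The likelihood ignores the 4 s deadline truncation (see above).
* No inter-trial variability parameters, collapsing bounds, or race-model
  alternatives; no WAIC/LOO — model comparison is DIC only, by design.
* The sampler is single-threaded random-walk MCMC: robust for this model
  family, but slower than gradient-based samplers for much larger spaces.
* Trait simulation is a copula construction, not a psychometric model.
* The generator's condition-level drift rates and start points are
  package defaults chosen to be realistic for two-alternative social
  decisions (drifts between −0.1 and 1.0 evidence units/s, boundary 1.8,
  non-decision time 0.35 s); they are not estimates from any dataset.
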