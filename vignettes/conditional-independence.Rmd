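---
title: "Combining evidence under conditional independence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining evidence under conditional independence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condind)
```

## The model

Let $C$ be a discrete outcome variable with states $c_1,\dots,c_M$, and
let $E^{(1)},\dots,E^{(N)}$ be evidence variables. If the evidence
variables are conditionally independent given $C$ —
$P(E^{(j)}, E^{(k)} \mid C) = P(E^{(j)}\mid C)\,P(E^{(k)}\mid C)$ for
all pairs — then the posterior over $C$ given all the evidence is fully
determined by the single-source posteriors and the prior:

$$
f(c) \;=\; \frac{\prod_{k=1}^{N} P(C=c \mid E^{(k)})}{P(C=c)^{\,N-1}},
\qquad
P(C=c \mid E^{(1)},\dots,E^{(N)}) \;=\; \frac{f(c)}{\sum_i f(c_i)} .
$$

`combine_many()` evaluates exactly this; `combine_two()` is the $N=2$
case. Two points deserve emphasis:

* **What is assumed.** Only the factorization given $C$. Unconditional
  independence of the evidence variables is neither implied nor
  required, and conditional independence carries no causal commitment:
  chains ($A \to C \to B$) and colliders ($A \to C \leftarrow B$) with
  the same numbers give the same answer.
* **What is bought.** Pairwise measurements replace an exponentially
  larger three-way (or $(N{+}1)$-way) table. Used in reverse, the rule
  is a parameter-free benchmark: if measured $P(C\mid A,B)$ departs from
  the prediction, the evidence sources interact.

Three companion forms are exposed. `posterior_odds()` rewrites the
two-source rule as a product of single-source odds times the *inverted*
prior odds, which makes the role of deviations from the prior explicit.
`linear_approx()` is the first-order expansion
$P(C{=}1\mid A,B)\approx P(C{=}1)+\epsilon_A+\epsilon_B$ valid for
small deviations $\epsilon$ and priors away from 0 and 1; it is exposed
for teaching and diagnosis, is never used internally, and is
deliberately not clipped to $[0,1]$ so that its failure mode is
visible. `combine_exclusive()` is the variant for experiments whose
"single-source" measurements are exclusive presentations (cue A alone,
cue V alone): there the no-cue success probability — chance — plays the
prior's role.

### Numerical choices

* Probability vectors must sum to 1 within $10^{-12}$; anything within
  tolerance is renormalized, anything further off is rejected. States
  are matched by label, never by position.
* A state with zero prior but positive evidence posterior is an
  inconsistency (a conditional probability cannot escape the prior's
  support) and raises an error rather than producing `Inf`.
* Jointly contradictory evidence (every unnormalized score zero) is an
  error, not `NaN`: the model gives no guidance there, and silently
  returning anything would hide a broken input.

## Count tables and the independence diagnostics

`joint_count_table()` stores **counts**, not probabilities: resampling
uncertainties need the raw observation numbers, and frequency trees are
naturally counts. `check_conditional_independence()` reports the
per-cell residuals $P(A,B\mid C) - P(A\mid C)P(B\mid C)$ with a default
pass tolerance of $10^{-9}$, appropriate for exactly constructed
tables; for empirical tables the residuals are reported as effect
sizes and no hypothesis test is attempted — formal tests of conditional
independence are a separate literature and out of scope here.
Zero-count conditioning slices are errors (conditioning) or skipped
with a warning (`predicted_vs_measured()`), never imputed.

The `g_factor()`,
$g(A,B) = P(A,B) \big/ \sum_c P(A\mid c)P(B\mid c)P(c)$, is the
multiplier that turns the predictability factorization into strict
conditional independence: all ones if and only if the condition holds,
*provided* the outcome variable has enough states,
$N_C \ge \min(N_A, N_B)$ (`identifiability_condition()`). Below that
threshold the defining linear system is underdetermined and
predictability is the weaker property.

## Resampling uncertainty

`resample_combined()` propagates the binomial sampling noise of each
input proportion through a combiner: every bootstrap replicate redraws
$k^* \sim \mathrm{Binomial}(n, \hat p)$ per input, recombines, and the
central percentile range of the replicates is the interval. Decisions
made here, where conventions are genuinely open:

* parametric binomial resampling at the observed proportion, with the
  percentile interval of the combined statistic (`n_boot` defaults to
  10\,000);
* the point estimate is always the plug-in value, never a resample
  summary;
* degenerate replicates (a resampled 0 or 1 in a denominator) are
  redrawn up to 100 times, then clamped to $[1/2n,\,1-1/2n]$ and
  flagged in the result — the alternative, silently dropping them,
  would bias the interval.

The test suite verifies ~95% empirical coverage of nominal 95%
intervals over 1\,000 independently simulated ground-truth systems with
observation counts of 2\,000/500/2\,000 (the scale of the multisensory
design below).

## Correlated binary outcomes

Two generators produce positively correlated uniforms that are then
thresholded against per-event probabilities (`sample_outcomes()`):

* **reset** (method "1"): each sample is replaced by a shared draw
  $\eta$ with probability $\alpha$. Every sample remains marginally
  Uniform(0,1), so target marginals are preserved *exactly* at any
  $\alpha$ — this is the default throughout.
* **shrink** (method "2"): $r_j = \alpha\eta + (1-\alpha)u_j$. The
  mixture is not uniform, so thresholded marginals are mildly
  distorted toward $1/2$; the generator is implemented as defined and
  the distortion documented rather than corrected, since its role is
  qualitative cross-checking.

A useful closed form, verified by brute-force simulation before being
frozen into the tests: under the reset method with both probabilities
at $1/2$, two events coincide beyond chance only when both reset to the
shared sample, so the phi coefficient equals $\alpha^2$ (not
$\alpha$). For panels whose event probabilities sit near 0 or 1 the
realized phi is attenuated further — relevant when interpreting the
age-averaged biomarker correlation matrices of `cohort_phi()`.

## The four application suites

### Repeated diagnostic tests

Sensitivity, specificity and prevalence give the predictive values
$r^+$ (PPV) and $r^-$ (NPV); with identical, conditionally independent
repetitions the $N$-source rule collapses to the closed form of
`repeated_test_posterior()`, which the suite checks against
`combine_many()` to $10^{-12}$. `simulate_repeated_tests()` induces
correlation *within subject across repetitions*, conditioning the
marginals on the true disease state — the only construction in which
"conditionally independent given disease" is exactly the $\alpha = 0$
case. Simulated empirical posteriors then sit on the diagonal against
the closed form at $\alpha=0$ (within 4 Monte-Carlo SE at $10^5$
subjects) and collapse to the single-test PPV at $\alpha=1$.

### Biological age from binary biomarkers

Each biomarker's probability of having switched state rises with age
along $P(B{=}1\mid a) = \Phi\!\big((a-\alpha)/\sigma\big)$ — the
erf-sigmoid written via the normal CDF. The age grid is the integers
0–100 with a flat prior of $1/101$; the grid is a discretization choice,
not a claim about real demography. Default marker parameters are drawn
as midpoint $\sim U(15, 85)$ years and width $\sim U(4, 20)$ years
(`"steep"` preset: $U(1,5)$), chosen once to produce a diverse but
plausible panel; they are fully configurable and seeded.

Bayes inversion gives per-marker posteriors $P(a \mid B)$, and
`age_posterior()` combines them with the rule above — the inferred
distribution of biological age. "Congruent" state vectors are prefixes
of ones in midpoint order (N+1 of them for N markers); the stress-test
comparisons (`compare_ci_vs_empirical()`) are restricted to congruent
vectors by default because incongruent ones can be observed only a
handful of times even in a $10^4$-per-age cohort, making normal-theory
Monte-Carlo error bars meaningless there. The empirical posterior
$P(a\mid \mathbf B)$ read off a cohort is valid because the cohort
samples every grid age equally, matching the flat prior; a non-flat
prior would require reweighting, which is why `simulate_cohort()` is
documented for the flat-prior design.

Two qualitative facts the tests verify: more markers (and steeper
curves) give lower-entropy congruent posteriors; and within-subject
correlation distorts the state-given-age probabilities noticeably more
than the age-given-state posteriors — the inference target is robust
to moderate violations of the assumption.

### Multisensory cue integration

`predict_multisensory()` maps a unisensory auditory performance level
and a visual performance curve to the multicue prediction via the
exclusive-condition rule, with chance (0.5 for the default
two-alternative design) in the prior's role. Chance is a design
constant and is not resampled. Default observation counts are 2\,000
auditory trials and 500 visual trials per stimulus level, matching the
simulated experiment the ribbons describe; the two demo auditory levels
are arbitrary, documented as such, and configurable. The prediction is
never below the better single cue when both are at or above chance and
saturates at 1 — both asserted on random grids.
`synth_psychometric()` is plumbing: a logistic in log-luminance from
chance to 1 used to generate end-to-end examples, not a fit to data.

### Selection history in oddball search

The behavioral model (`simulate_session()`) draws a target color (2)
and location (4) uniformly per trial and makes either an informed
choice — probability $p_I = \mathrm{logistic}(s(i_T) - 0.9)$, correct
with probability 0.95, lapses uniform over the three non-target
locations — or a bias-weighted guess. After every trial the location
biases decay and the target's bias is boosted
($b \leftarrow 0.5b + 0.1$, then $b_{j_T} \mathrel{+}= 1$); the color
sensitivities decay ($s \leftarrow 0.4 s$) and are pushed apart
($+2/-2$) **only after correct choices**. That gating is the designed
color-by-outcome interaction; bias updates, applying regardless of
outcome, leave location and outcome independent. The two update blocks
touch disjoint state, so their within-trial order is immaterial.

Open details fixed here: initial state $s=(0,0)$, $b=(1,1,1,1)$ (the
dynamics forget it within tens of trials); history labels read
most-recent-first ("SD" means the immediately preceding trial matched);
for location histories all three non-target locations count as
different, repeated or not; binomial intervals are Clopper–Pearson; the
benchmark regression is ordinary least squares of predicted on
measured, excluding points whose 95% interval spans more than 0.15.

A 100,000-trial session (the reference analysis size, about two
seconds) shows the characteristic selection-history pattern the test
suite asserts: color-repetition benefit rising from roughly 0.61 (S) to
0.78 (SSSS) against a ~0.50 success prior, a location-repetition
benefit, a modest outcome effect, and a joint same-color/after-correct
success probability far above its conditional-independence prediction
(≈0.80 vs ≈0.65) with regression slopes well below 1 — while
location-by-outcome stays on the diagonal with slope compatible
with 1. One known structural limitation: accuracy after four location
repeats is capped near 0.85 by the bias-update constants themselves
(the guess mass on a four-times-repeated location converges to
$2.2/2.8 \approx 0.79$, and the informed-choice rate in those trials
stays near its marginal), so this bin saturates around 0.81 at the
default parameters.

## Problem sizes and what the tests show

The suite runs the full oracle check (1\,000 random conditionally
independent joint tables against brute-force conditionals, agreement to
$10^{-10}$), one 100,000-trial oddball session, $10^5$-subject
diagnostic simulations, a $10^4$-per-age three-marker recovery cohort,
and the 1\,000-replication coverage study — about a minute in total.
All simulations are seeded and bit-reproducible.

Passing these tests shows the implementation is internally consistent
and that the combination rule is exact when its assumption holds *by
construction*. It does not show that any particular real-world
evidence sources are conditionally independent — that is an empirical
question the diagnostics are designed to ask of real data, and the
correlated simulators exist precisely to illustrate how violations
manifest.
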