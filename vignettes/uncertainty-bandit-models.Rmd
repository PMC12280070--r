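---
title: "Estimation-uncertainty in bandit learning and feedback-free choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation-uncertainty in bandit learning and feedback-free choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kalmanbandit)
```

## The scientific problem

In a two-armed bandit with *partial feedback* — only the chosen option's
outcome is revealed — the better ("Good") option of a pair is sampled far
more often than the worse ("Bad") one. Sampling is what reduces an
option's *estimation-uncertainty*: the standard deviation of the belief
about its value. A Bad option therefore exits the learning phase not only
with a lower expected value but also with a much higher
estimation-uncertainty, and the two are confounded at the behavioral
level. This package implements the computational apparatus needed to ask
whether that acquired uncertainty keeps shaping decisions later, in a test
phase where no feedback (and hence no information gain) is available:
task simulators, a 6 x 2 family of learning and decision models,
subject-level fitting, random-effects model comparison, model and
parameter recovery, and the model-agnostic sampling-rate statistics.

## Task designs

The main design (`make_main_design()`) has five conditions. Each condition
is one pair of options; the Good option draws positive feedback with
probability 0.75, the Bad option with probability 0.25. What "positive"
is worth depends on a per-condition context probability `p_appetitive`
(1.0, 0.75, 0.5, 0.25, 0.0): with that probability the trial's feedback is
drawn from an appetitive mapping (positive/negative = +1/0 currency
units), otherwise from an aversive mapping (0/-1). Expected values
therefore rise linearly in `p_appetitive` while the Good-minus-Bad gap is
0.5 everywhere, and outcome entropy is inverse-U-shaped in
`p_appetitive`:

```{r}
d <- make_main_design()
design_option_table(d)[design_option_table(d)$block == 1,
                       c("condition", "role", "ev", "entropy")]
```

Learning runs over three blocks of fresh stimuli; each block presents all
five pairs in 16-trial streaks (240 trials). The condition order of block
1 is a random permutation, block 2 an independent one, and block 3
reverses block 1. The feedback-free test phase recombines the learned
options: per block all 10 good-vs-good and all 10 bad-vs-bad pairings of
the five conditions, plus 30 cross-block good-vs-bad pairs of the same
condition, each unique pair shown twice in random order (180 trials).

The two validation designs (`make_validation_design()`) encode the public
four-pair magnitude experiments: pairs `A1B1`/`A2B2` pay +10 on reward and
`C1D1`/`C2D2` pay +1 (non-reward 0, reward probability 0.75/0.25 for
Good/Bad), 30 learning trials per pair, and test pairs
`A1C1`/`B1D1`/`A2D2`/`B2C2` shown 30 times, inter-mixed or block-wise.

Outcome generation draws, independently on every feedback, the context
(Bernoulli `p_appetitive`) and the valence (Bernoulli of the role's
positive-feedback probability) and maps the pair to its magnitude; this
factorization reproduces every stated marginal probability, and
per-trial i.i.d. draws are used rather than pre-generated outcome
sequences. Screen side is randomized per trial and recorded but has no
effect in any model.

## Learning models

All models maintain an expected value `q_i` per option, initialized at
`q0`, the mean of the design's outcome alphabet under equal probabilities
(0 for the main design's {-1, 0, +1}). Updates occur only on learning
trials, for the chosen option unless stated otherwise:

* **1alpha** - Q-learning, `q <- q + alpha * (R - q)`.
* **2alpha** - separate rates for positive and negative prediction
  errors; a zero prediction error applies neither branch and updates
  nothing.
* **select_reject** - the rejected option is updated with the
  reverse-signed prediction error of the selected one, letting an agent
  learn the "badness" of what it avoids.
* **relative** - outcomes are centred on a learned per-pair context value
  `V_c` which tracks `(R + q_rejected)/2`; `V_c` starts at 0 (a neutral
  baseline; the option update precedes the context update within a
  trial).
* **range** - outcomes are normalized to `(R - R_MIN)/(1 + R_MAX -
  R_MIN)` with per-pair trackers that start at `R_MAX = R_MIN = 0`; 0 is
  the omnipresent non-reward outcome in all three designs, and the
  trackers move toward outcomes that exceed them at rate `alpha_r`. The
  initialization is configurable in principle (an alternative convention
  starts the trackers at the first observed outcome), but 0 is the
  package default and the one used everywhere here.
* **kalman** - a Kalman filter whose learning rate
  `alpha_i = sigma_i^2 / (sigma_i^2 + sigma0^2)` is per-option and
  dynamic. The estimation variance shrinks as
  `sigma_i^2 <- sigma_i^2 - alpha_i * sigma_i^2`, so starting from
  `sigma0^2` it equals `sigma0^2 / (k + 1)` after `k` observations and the
  value estimate is the pseudo-count running mean `(q0 + sum R)/(k + 1)`.
  There is no free learning parameter. `sigma0` is the standard deviation
  of the outcome alphabet under equal probabilities (`sqrt(2/3)` for the
  main design; for the validation designs the experiment-wide alphabet
  {0, 1, 10} is used, giving about 4.497 — a per-pair alphabet would be a
  defensible alternative and the belief constants are exposed on the
  belief object).

The environment is static, so the unobserved option's variance is left
unchanged (no diffusion term) and uncertainty only ever decreases with
sampling — which is exactly what ties `sigma` monotonically and
negatively to the sampling rate.

Any non-Kalman learner can be *composed* with the Kalman uncertainty
recursion (`attach_uncertainty_tracker()`, or simply the `_qu` model
variants): its `q` follows the base rule while `sigma` follows the
recursion for the chosen option. The recursion depends only on the choice
sequence, so a tracked learner's `sigma` trajectory is identical to the
Kalman learner's on the same choices.

## Decision models

Choice probabilities are a softmax over utilities (computed as the
logistic of the utility difference; with weights bounded at 20 and
magnitude-10 outcomes, naive exponentiation would overflow). Decision
model **Q** uses `u = q * beta_q`; model **QU** adds the uncertainty,
`u = q * beta_q + sigma * beta_u`, so `beta_u < 0` expresses uncertainty
aversion. There is no lapse parameter. Crossing six learners with two
deciders yields the 12-model family (`all_model_ids()`).

## Fitting and model comparison

Each subject and phase is fitted by MAP under independent Gaussian
priors with variance 16.25 for every parameter. Learning rates live on
[0, 1] and are fitted on the logit scale, where the prior (centred on
logit(0.5) = 0) applies — the convention of hierarchical fitters for
bounded rates, and the space in which the Laplace evidence is computed.
This choice matters: computing the evidence in native rate space
penalizes models whose rate MAP sits on a bound so harshly (the
objective is kinked there) that nested-model recovery breaks; on the
logit scale the same fits are well-behaved. Decision weights are fitted
in native space within [-20, 20], prior mean 0. Optimization is bounded
L-BFGS-B from 10 restarts (prior mean plus uniform draws; weight starts
are confined to [-5, 5] and rate starts to logit rates in roughly
[0.08, 0.92], where the likelihood is not saturated). For the test phase the
subject's own learning trials are replayed first — under partial feedback
the subject's choices determine what was sampled, hence the frozen
beliefs — and only test choices are scored; any learning-rate parameters
are fitted jointly with the test-phase weights. For Kalman-family models
the belief trajectory does not depend on the fitted parameters at all,
making both phases a concave logistic-regression problem in the decision
weights; the MAP is then unique.

Model evidence is a Laplace approximation at the MAP (finite-difference
Hessian, ridge-regularized and flagged if not positive definite), and
group-level comparison is variational random-effects Bayesian model
selection over the subjects x models evidence matrix, with exceedance
probabilities (analytic for two models, Dirichlet Monte-Carlo otherwise)
protected by the Bayes omnibus risk. This MAP + Laplace + RFX-BMS stack
is a deliberate, documented stand-in for full hierarchical Bayesian
inference: it produces the same statistical outputs (model frequencies,
protected exceedance probabilities) at desk scale. The one systematic
difference worth knowing about is the absence of hierarchical shrinkage,
which makes per-subject estimates — and therefore recovery correlations —
somewhat noisier than a hierarchical fitter would report; the
package's own recovery checks bound this from below rather than matching
a hierarchical fitter's exact numbers.

McFadden's pseudo-R^2 is `1 - LL_model / LL_null` with the null choosing
each option with probability 0.5.

## Synthetic cohorts and recovery

`generate_cohort()` simulates virtual participants end to end. Generating
parameters are drawn uniformly: rates over [0, 1], `beta_q` over
[0.5, 6] and `beta_u` over [-8, 0]. These ranges bracket the fitted group
means of the three experiments the designs emulate (learning-phase
`beta_q` around 2.9 and `beta_u` around -1.1; test-phase `beta_q` around
1.2 and `beta_u` around -5.5) and are recorded in every recovery report.
Test-phase decision weights are drawn independently of the learning-phase
weights by default — the experiments fit the two phases separately, and
independent draws are the conservative choice for test-phase recovery;
set `independent_test_betas = FALSE` to reuse the learning weights. Each
subject gets an RNG stream derived from the master seed, so cohorts are
reproducible bit for bit.

`run_parameter_recovery()` re-fits the generating model and reports the
generating x recovered correlation matrix. By default the re-fit uses a
two-pass empirical-Bayes scheme: a first pass under the broad priors, a
second under a group prior estimated from the first-pass estimates
(standard deviation floored at 0.5 on the fitting scale), with model
evidences always taken from the broad-prior pass so model comparison is
unaffected. This emulates the shrinkage a fully hierarchical fitter
applies and stabilizes weakly identified subjects. `run_model_recovery()` builds
the confusion matrix: for each generating model, simulate a cohort, fit
all 12 candidates, and take the random-effects model frequencies as the
row. For test-phase model recovery, the learning history is generated
once per cohort by the winning learning model; each generating model then
replays that history with its own sampled learning parameters to form
beliefs and simulates only the test choices.

What the generator emulates: partial feedback, the resulting asymmetric
sampling rates and uncertainties, and a feedback-free test phase over
recombined pairs. What it does not emulate: reaction times, forgetting or
working-memory effects across blocks, payment accounting, or any
non-stationarity in the outcome process. Passing recovery and sign-pattern
checks on these cohorts shows the inferential machinery is sound under
the task's statistical structure; it cannot certify any particular claim
about real participants.

## Model-agnostic statistics

`learning_performance()` is the proportion of Good choices per pair;
`sampling_rates()` restates it as the exact bookkeeping identity
(Good rate = performance, Bad rate = its complement).
`test_selection_rates()` scores each unique test pair by the proportion
of choices of its reference option (the Good option in mixed pairs, the
option from the more valuable condition otherwise).
`perf_selection_correlations()` correlates, across subjects,
block-matched differences in learning performance with test-phase
selection rates, per pairwise comparison and pooled by pair type: with
uncertainty-averse agents the good-vs-good correlations come out positive
and the bad-vs-bad ones negative, the signature that selection of Bad
options tracks their sampling rate rather than their expected value.
`pairwise_bias_table()` provides the group-level biases against
ground-truth expected-value and entropy differences. The linear
mixed-effects ANOVAs of the original analyses are routine statistics and
are not re-implemented; the per-comparison correlation tables and their
pooled contrasts cover the same scientific content.

`permutation_delta_r()` tests a difference between two dependent
correlations by shuffling the actual vector (1000 permutations by
default), reporting the two-tailed p (ties count as extreme; for
continuous statistics this coincides with the strict inequality almost
surely), the null's 95% interval, and the standardized effect size
`(observed - null mean) / null sd`. The shuffle destroys any dependence
between the actual vector and both fitted vectors, so the scheme is exact
under the null in which the actual values are uninformative about either
fit; when both fits carry equal but nonzero information the scheme
follows the shuffling procedure as literally specified, whose null is approximate. The
type-I calibration in the test suite therefore uses the exchangeable
null. Shuffling is across subjects, as the procedure is literally
described.

## Numerical choices and problem sizes

Log-probabilities use the stable `-log1p(exp(-|d|))` form throughout.
The trial replay that backs every likelihood is compiled (C++), with a
pure-R reference implementation kept in the package and asserted equal to
1e-12 in the tests. Degenerate inputs fail loudly: corrupt histories,
constant vectors in correlation or permutation routines, and non-finite
evidences are rejected with informative errors rather than propagating
NaN.

The package's own validation runs use 200 virtual subjects for parameter
recovery, 50 subjects per generating
model for the 12 x 12 confusion matrix (with 5 optimizer starts per fit
there — the 7200 recovery fits are averaged over subjects by the
random-effects step, so occasional sub-optimal restarts wash out, while
ordinary single-subject fits keep the 10-start default), and 500
replicates x 1000 permutations for the type-I calibration — sizes chosen
so the full check suite completes in well under half an hour on a single
core while keeping Monte-Carlo error small relative to the tolerances
asserted.

## Known limitations

* Per-subject fitting recovers decision weights with correlations in the
  low 0.9s for the learning phase but only the high 0.8s for the
  test-phase uncertainty weight under the broad generating ranges. The
  test-phase weights are partially collinear — options with high value
  are exactly those with low uncertainty — and the likelihood saturates
  for extreme `beta_u`, so per-subject estimates are attenuated; because
  the resulting shrinkage is close to uniform, the empirical-Bayes pass
  cannot raise this particular correlation (Pearson's r is invariant to
  affine transformations). Narrower, phase-specific generating ranges
  recover better.
* Exceedance probabilities for more than two models are Monte-Carlo
  estimates (2e5 draws by default; the seed is exposed).
* The designs assume a static environment; restless-bandit extensions,
  uncertainty diffusion and eligibility traces are out of scope.
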