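# kalmanbandit

Simulation and model-based analysis of two-armed bandit reinforcement
learning with a feedback-free test phase, centred on
**estimation-uncertainty**: the standard deviation σ of an option's value
estimate, which shrinks the more often the option is sampled.

## The problem

Under partial feedback (only the chosen option's outcome is revealed),
the Good option of a pair is sampled far more than the Bad one, so Bad
options end learning with both lower expected value and higher
estimation-uncertainty — two confounded quantities. This package provides
the tools to disentangle them: when options learned in different pairs
are later recombined and choices are made without feedback, an
uncertainty-averse decision maker avoids the rarely sampled (high-σ)
option even when its expected value is not lower. The tell-tale signature
is that across subjects, differences in learning performance correlate
*positively* with selection rates in good-vs-good test pairs but
*negatively* in bad-vs-bad pairs (the Bad option of a well-learned pair
is precisely the one sampled least).

## Models

Six learning rules — Q-learning with one (`1alpha`) or two (`2alpha`)
rates, selected/rejected updating (`select_reject`), contextual centring
(`relative`), range normalization (`range`), and a Kalman filter
(`kalman`) with per-option dynamic learning rate
α<sub>i</sub> = σ<sub>i</sub>² / (σ<sub>i</sub>² + σ₀²) and variance
recursion σ<sub>i</sub>² ← σ<sub>i</sub>² − α<sub>i</sub>σ<sub>i</sub>² —
crossed with two softmax decision rules:

* **Q**:  u = Q·β<sub>Q</sub>
* **QU**: u = Q·β<sub>Q</sub> + σ·β<sub>U</sub>  (β<sub>U</sub> < 0 ⇒ uncertainty aversion)

with p(choose i) = e<sup>u_i</sup> / (e<sup>u_i</sup> + e<sup>u_j</sup>).
Any learner can be composed with the Kalman σ-recursion, so uncertainty
can enter decisions under every learning rule. Subjects are fitted by MAP
(Gaussian priors, mean 0.5 for rates / 0 for weights, variance 16.25;
rates bounded to [0, 1], weights to [−20, 20]), model evidence is a
Laplace approximation, and groups are compared by random-effects Bayesian
model selection with protected exceedance probabilities. Model- and
parameter-recovery harnesses and the model-agnostic sampling-rate
statistics (including a permutation test for differences between
correlations, with standardized effect sizes) complete the pipeline.

## Worked example

Simulate 20 uncertainty-averse virtual participants through the main
five-condition task, fit the test phase with and without the uncertainty
term, and compare models:

```r
library(kalmanbandit)
design <- make_main_design()
cohort <- generate_cohort(20, "kalman_qu", design, seed = 42)

fits_qu <- fit_dataset("kalman_qu", cohort$trials, "test", design, seed = 1)
fits_q  <- fit_dataset("kalman_q",  cohort$trials, "test", design, seed = 1)
bms <- rfx_bms(cbind(kalman_qu = fits_qu$log_evidence,
                     kalman_q  = fits_q$log_evidence))
bms
#> <bms> 2 models, BOR = 0.00177
#>            kalman_qu kalman_q
#> frequency     0.9400    6e-02
#> exceedance    1.0000    0e+00
#> protected     0.9991    9e-04

perf_selection_correlations(cohort$trials)$pooled
#>   pair_type mean_pearson_r
#> 1       BvB     -0.3724922
#> 2       GvB      0.5481496
#> 3       GvG      0.5111263
```

The generating model (with uncertainty) wins the group comparison with a
protected exceedance probability of 0.999, and the pooled across-subject
correlations show the opposing sign pattern — positive for good-vs-good,
negative for bad-vs-bad — that expected values alone cannot produce.

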