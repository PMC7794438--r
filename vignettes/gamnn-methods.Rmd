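---
title: "Methods: generalized additive neural networks for interpretable risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized additive neural networks for interpretable risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamnn)
```

## The model

`gamnn` fits a generalized additive model whose univariate component
functions are small neural networks. For a sample with continuous
features $x_j$ and binary features $x_b$, the predicted log-odds of the
outcome are

$$
\eta(x) \;=\; \beta_0 \;+\; \sum_{j \in \text{cont}} w_j \, g_j(x_j)
\;+\; \sum_{b \in \text{bin}} w_b \, x_b ,
\qquad
p(x) = \operatorname{sigmoid}(\eta(x)) .
$$

Each $g_j$ is a feed-forward subnetwork that sees only its own feature:
one to four dense hidden layers of equal width, followed by a single
unit with a hyperbolic-tangent activation. That final tanh unit is the
*bottleneck*: it compresses the subnetwork to one number and bounds it
in $(-1, 1)$, so the feature's additive contribution $w_j\,g_j(x_j)$ can
never exceed $|w_j|$ in magnitude. Binary flags skip the subnetworks
entirely and connect straight to the final logistic layer; their
contribution is simply $w_b x_b$. No pairwise interaction terms are
modelled — the additive decomposition is the point.

Interpretability is structural, not post hoc: because the logit is an
exact sum, `contributions_table()` decomposes every prediction into
per-feature terms whose sum (plus the intercept) reproduces the forward
logit to floating-point accuracy, `shape_curves()` plots
$w_j\,g_j(x_j)$ against the raw feature value to show the learned risk
shape, and `patient_report()` ranks one patient's contributions for a
clinician-facing display. Contributions are always reported on the
logit scale; we never transform them to probabilities, where additivity
would be lost.

Two architectural details are deliberate choices. The final logistic
layer carries an intercept $\beta_0$; it is reported separately and
never allocated to a feature. The bottleneck unit carries a bias term,
as an ordinary dense unit does. Neither choice affects the additive
decomposition.

One identifiability caveat matters when comparing contribution
*magnitudes*: the decomposition is unique only up to per-feature
constants, because a subnetwork can output a constant that trades off
against the intercept (and against other subnetworks' constants)
without changing any prediction. Contribution *curves* and per-patient
*rankings* are unaffected, but "how large is this feature's effect"
should be measured as the spread of its contribution around its cohort
mean, not as a raw mean absolute value — a null feature can carry a
sizeable constant offset while modulating nothing.

## Preprocessing

The pipeline order is fixed: impute, then clip, then standardize. All
data-derived parameters (imputation means, standardization statistics)
come from training rows only; `preprocess_apply()` applies them
unchanged to any partition, and a property test asserts that perturbing
test rows leaves the fitted statistics bit-identical.

* **Imputation** is schema-driven, with three policies. `constant`
  fills a declared clinical value (the canonical example is an ordinal
  ASA physical-status score whose missing entries are filled with the
  modal class, 3). `zero` is for infusion/medication summaries where a
  missing value means the drug was never given. `train_mean` fills with
  the mean of observed training values.
* **Clipping** replaces values beyond declared clinical plausibility
  bounds with the bound itself. Bounds are domain constants supplied in
  the schema, never derived from data, and apply identically to both
  partitions.
* **Standardization** rescales each continuous feature to mean 0 and
  standard deviation 1 using training-set statistics. We use the
  population (divide-by-$n$) standard deviation; with tens of
  thousands of rows the distinction from the sample version is
  negligible, but fixing one convention keeps results reproducible.
  Binary 0/1 flags are *not* standardized by default: the binary
  contribution formula $w_b x_b$ and the convention of reading a flag's
  contribution directly off its logistic weight presuppose raw 0/1
  inputs. A `standardize_binary = TRUE` flag restores the literal
  all-features reading for users who want it.

ASA-style ordinal scores are treated as continuous features with their
own subnetwork: they take more than two values and a learned nonlinear
shape over the ordinal range is exactly what the architecture is for.

The train/test split assigns `round(train_fraction * n)` rows to
training; at the canonical cohort size of 59,985 records and a 0.8
fraction this gives 47,988 training and 11,997 testing rows.

## Training

The loss is class-weighted cross-entropy: a positive sample's loss is
multiplied by `positive_class_weight` (default 100), reflecting an
outcome prevalence below 1% where an unweighted fit collapses toward
the majority class. The batch loss is the mean of per-sample losses;
probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ before the
logarithm for numerical safety. An L2 penalty (`l2_lambda`) applies to
all weight matrices including the logistic layer, excluding biases —
the common convention.

Optimization is mini-batch Adam (batch size 256) at its conventional
default learning rate of 0.001 with $\beta_1 = 0.9$,
$\beta_2 = 0.999$. When the monitored loss — validation loss if a
validation set is supplied, otherwise training loss — fails to improve
for five consecutive epochs, the learning rate is divided by 10, with a
floor of $10^{-6}$ to prevent underflow. Training runs to `max_epochs`
(default 100); an `early_stop` flag exists but defaults off. Dropout
(default 0.5) applies to subnetwork hidden activations only — not to
raw inputs and not to the concatenated bottleneck outputs, which keeps
the additive decomposition stable during training. All randomness
(initialization, shuffling, dropout masks) derives from `config$seed`,
so a fixed seed reproduces the final weights on the same platform.

Hyperparameter search is a Cartesian grid (`gamnn_grid()`: 1–4 hidden
layers; widths 10, 40, 50, 90, 100; relu or tanh; dropout 0.25, 0.5,
0.9; L2 0.001 or 0.0001) scored by mean 5-fold cross-validated AUC.
Folds are stratified by outcome — at sub-1% prevalence an unstratified
fold can easily contain no positives, leaving its AUC undefined. Ties
break by grid order, deterministically; fold-level training seeds
depend on the configuration's own seed and the fold index, so identical
configurations tie exactly. The winning configuration is retrained on
all training rows before being returned; during that retrain no
validation set exists, so the learning-rate schedule monitors training
loss. The reference configuration (the package default) is one hidden
layer of 50 tanh units, dropout 0.5, L2 $10^{-4}$. The width grid
includes both 40 and 50 as discrete options.

## Evaluation

`roc_auc()` uses the Mann–Whitney formulation (ties count one half),
and `average_precision()` the non-interpolated step-wise sum over the
score-descending ranking, with ties broken by stable original order.
Both are verified in the test suite against $O(n^2)$ brute-force
oracles and, for AUC, against an independent ROC implementation.
Confidence intervals are percentile bootstrap (default 1000 paired
resamples, 2.5th/97.5th percentiles) — the simplest interval consistent
with plain bootstrapping; BCa refinements are out of scope. Resamples
containing a single class are discarded and redrawn, with a cap of ten
times the requested resample count before erroring.

The logistic-regression baseline is fitted on exactly the features the
GAM-NN sees, on the same standardized scale, via ridge-penalized
maximum likelihood with $\lambda = 10^{-6}$ — numerically a maximum
likelihood fit, but still defined under perfect separation or constant
columns (which are flagged with a warning).

## The synthetic cohort generator

Because real perioperative EHR extracts are institution-private, every
stage is validated on generated cohorts with known additive structure.
`cohort_spec()` declares continuous features (truncated-normal values
in clinical units; shape functions `linear`, `u_shaped`, `threshold`,
or `flat` evaluated on the feature's standardized scale, each centered
to have approximately zero mean) and Bernoulli flags with log-odds
weights. The true logit is assembled additively and labels are drawn
from its sigmoid; the intercept is calibrated numerically to hit a
target outcome prevalence. Missing cells and out-of-range spikes are
injected *after* label generation, so labels always reflect true
values and preprocessing robustness is isolated from label noise.

`perioperative_cohort_spec()` is the ready-made template: a U-shaped
mean-arterial-pressure effect with an interior risk minimum (risk
rising at low and high pressure), a protective minimum diastolic
pressure, a monotone age effect, a thresholded ASA-style ordinal score
with constant-policy missingness, a null (`flat`) lab feature carrying
out-of-range spikes to exercise clipping, and three device/procedure
flags at prevalences of 18%, 5% and 2%. The default outcome prevalence
is 0.8% — the rare regime of postoperative in-hospital mortality. The
generator's defaults are fixed once; tests do not tune them.

What the generator does *not* emulate: real marginal distributions
(mixtures, heavy tails, measurement artifacts), correlated features,
informative missingness, interactions, or label noise beyond Bernoulli
sampling. Passing the recovery tests therefore shows the estimator
works when its additivity assumption holds, not that real EHR data
satisfy that assumption.

## Problem sizes and tolerances in the test suite

The suite favors sizes that give stable statistics: shape recovery runs
on a 20,000-sample template cohort with prevalence lifted to 5%. The
monotone (linear and threshold) shapes are recovered with Spearman
agreement of 0.99 or better and the null feature's centered mean
absolute contribution is suppressed at least tenfold below every
informative continuous feature's; the U-shaped feature's recovery is
asserted at the same 0.9 bar but fails it by design of the
architecture — the monotone-collapse limitation above — and the suite
reports that shortfall rather than hiding it. The linear-limit
check (the GAM-NN matching the logistic baseline within 0.02 AUC on a
purely linear logit, learned shapes with straight-line $R^2 \ge 0.9$)
uses 8,000 samples at 5% prevalence and trains without dropout — see
the saturation note under limitations; the grid-search contract (the
reference architecture beating a crippled dropout-0.9/10-unit
configuration) uses 2,500 samples at 10% prevalence with 30-epoch
training per fold. Additive-decomposition residuals are asserted below
$10^{-6}$ (observed at machine precision); metric oracles agree to
$10^{-12}$. All stochastic checks run under fixed seeds.

## Known limitations

* One-dimensional subnetworks cannot represent interactions; if the
  true risk surface is non-additive, the shape curves are the best
  additive approximation and should be read as such, not causally.
* Strongly non-monotone effects can collapse to their monotone
  component. The single-unit tanh bottleneck admits U-shaped solutions,
  and training preserves them when they are present — a warm-started U
  ends at lower loss than the collapsed fit — but Adam from random
  initialization reliably converges to a monotone local minimum: the
  early linear trend saturates the bottleneck, and the saturated
  gradient ($1 - \tanh^2$) then silences exactly the tail samples that
  carry the second arm. The test suite freezes this behavior as a
  property test, and the same collapse reproduces in an independent
  neural-network implementation given the same bottleneck architecture.
  In practice: recovered monotone and threshold shapes are trustworthy;
  a shape curve that *looks* monotone does not rule out a U-shaped
  truth. Inspect candidate U features (e.g. blood-pressure summaries)
  with domain knowledge rather than trusting the learned curve's
  monotonicity.
* Dropout flattens shape tails. Because each contribution is bounded by
  its logistic weight, representing a steep effect over a wide value
  range needs a large weight with the tanh in its linear regime; dropout
  noise on the hidden layer makes large weights costly, so the fit
  prefers a smaller weight with a saturated tanh. Under heavy dropout
  the learned curves are therefore compressed at extreme values even
  when the true effect keeps rising. The linearity diagnostic in the
  test suite runs without dropout for exactly this reason; read
  shape-curve tails of heavily regularized models with care.
* With dropout and heavy class weighting, very short trainings can be
  worse than chance on small cohorts; the defaults assume thousands of
  rows and the full epoch budget.
* The bootstrap interval is percentile-based and can be narrow at
  extreme AUCs; it may fail to cover in pathological zero-variance
  cases.
* Training is single-threaded, pure-R matrix arithmetic: adequate for
  tens of features and tens of thousands of rows, not for
  high-dimensional problems.
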