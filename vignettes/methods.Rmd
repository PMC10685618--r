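---
title: "Stacked CTG classification with Kernel SHAP explanations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked CTG classification with Kernel SHAP explanations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiotocography (CTG) records fetal heart rate and uterine contractions and
is summarized, in routine practice, as a table of numeric features — baseline
heart rate (LB), accelerations per second (AC), percentage of time with
abnormal short-term variability (ASTV), prolonged decelerations (DP),
histogram statistics (Mean, Mode, Width, ...) and so on — annotated by
obstetricians with a fetal-state label: Normal, Suspicious or Pathologic
(NSP). The classification task is heavily imbalanced (roughly 78/14/8 percent
in the widely used public feature table of 2126 records with 21 features),
and the clinically costly mistake is calling a suspicious or pathologic trace
normal.

`ctgstack` implements two things on top of that task:

1. a **stacked ensemble with mixed meta-features**: base learners emit class
   *probabilities* (not hard labels), and the meta learner is trained on those
   probabilities concatenated with the original feature vector;
2. a **from-scratch Kernel SHAP explainer** that attributes each prediction
   additively to the input features, validated coordinate-by-coordinate
   against an exact brute-force Shapley oracle.

## Preprocessing: zeros-mean normalization

Every feature is transformed to `x* = (x - mu) / sigma` with `mu` and `sigma`
estimated per column. Choices the definition leaves open, and what this
package does:

* **Population vs sample standard deviation.** The divide-by-*n* population
  form is the default; `fit_normalization(sample_sd = TRUE)` switches to
  divide-by-*n−1*. For the sample sizes involved the difference is far below
  any decision threshold.
* **Constant features.** `sigma = 0` makes the transform undefined; the
  package maps such columns to 0 and warns, which keeps constant features
  inert instead of propagating NaN.
* **Fit-on-train only.** Normalization parameters are always fitted on the
  training portion of a split and applied to held-out data. Fitting on the
  pooled data before splitting would leak held-out information into training;
  the effect is small but the leak-free protocol costs nothing.

Tree ensembles are scale-invariant and tolerate raw features; the kernel
classifier and the network require the normalized scale. The pipeline
normalizes once and feeds all learners the same matrix.

## The stacked ensemble

Base learners (defaults, all hyperparameters config-exposed):

* `kernel_margin` — radial-basis SVM, cost 1, with post-hoc probability
  calibration (Platt scaling as provided by libsvm);
* `boosted_trees` — gradient boosting, 200 rounds, learning rate 0.1,
  maximum depth 3;
* `bagged_trees` — probability random forest, 200 trees.

Meta learner: `backprop_net`, a single-hidden-layer feed-forward network (32
logistic hidden units as implemented by `nnet`, softmax output) trained by
error backpropagation for up to 500 epochs. `nnet` offers
no early stopping on a validation split, so weight decay (`1e-4`) serves as
the regularizer instead; with meta-feature dimensionality around 30 this is
the conventional safeguard against overfitting a small network.

The four meta-feature **strategies** implemented by `build_meta_features()`:

| strategy | meta input | width |
|---|---|---|
| `labels` | one-hot base predictions | B·C |
| `probabilities` | base class probabilities | B·C |
| `labels_plus_features` | one-hot + original features | B·C + M |
| `probabilities_plus_features` | probabilities + original features (default) | B·C + M |

Design choices worth stating:

* **Out-of-fold meta features.** The meta learner's training inputs are
  produced by an internal stratified k-fold (default `oof_folds = 5`): each
  training row's base output comes from base models that never saw that row.
  Training the meta learner on resubstitution outputs would let it exploit
  base-learner overfitting; out-of-fold generation is the standard
  leakage-free construction, and the fitted model retains an audit record
  (`$audit`) proving the discipline row by row.
* **One-hot labels.** "Category label" strategies encode predictions as
  one-hot vectors rather than integer codes, avoiding an artificial ordering
  of fetal states; the width algebra above assumes this.
* **Refit on full training data.** After the meta learner is trained, base
  learners are refit on the entire training partition for inference, so
  prediction-time base models see all available data.
* **Scaling of the meta input.** The probability block already lives in
  [0, 1]; the appended original features are the normalized features, which
  are standardized by construction. No second standardization is applied.
* **Argmax ties** break to the lowest class index, making predictions
  deterministic.
* **No class reweighting by default**; a `class_weights` hyperparameter
  exists for the kernel and forest families but defaults off.

All randomness flows from a single integer seed per call, fanned out to
sub-components by a seeded draw (`derive_seeds`); no function depends on the
global RNG state.

## Evaluation

`compute_metrics()` implements accuracy as fraction-correct (trace of the
confusion matrix over the total), and per-class precision, recall and F1 by
one-vs-rest reduction, with F1 the harmonic mean of precision and recall.
The summary "average F1" is the **macro** (unweighted) mean by default —
the robust choice under class imbalance — with prevalence-weighted values
also reported. Zero-denominator cases (a class never predicted, or absent)
score 0 and are flagged rather than yielding NaN.

Confusion matrices are stored predictions × real classes;
`normalize_confusion()` divides each column by its real-class total, so the
diagonal is per-class recall (the class-conditional convention used for
reporting hold-out results).

`cross_validate()` averages the per-fold metric values (fold-level
averaging, not prediction pooling; a pooled mode would change little but the
fold-averaged protocol is the one implemented and tested). Folds are
stratified by default; whether stratification is the "right" historical
choice is unknowable from outside, but stratification is the only way to
guarantee every fold contains the rare pathologic class at these sample
sizes. `compare_strategies()` forces identical fold assignments and seeds
across the four strategies so the comparison is paired.

## Kernel SHAP

For a model output `f` and an instance `x` with `M` features, the explainer
fits the additive surrogate

```
g(z') = phi0 + sum_i phi_i z'_i,   z' in {0,1}^M
```

by weighted least squares over feature coalitions `z'`, minimizing
`sum_z [f(h(z')) - g(z')]^2 * pi(z')` with the Shapley kernel

```
pi(z') = (M - 1) / (choose(M, |z'|) * |z'| * (M - |z'|)).
```

Implementation decisions:

* **Masked evaluation `h(z')`.** Absent features are replaced by background
  (reference) values: for each background row, a hybrid row takes `x` where
  `z' = 1` and the background row elsewhere, and `f` is averaged over the
  background (the interventional convention). The default background is a
  seeded uniform subsample of 100 training rows; a single-reference mode
  falls out of passing a one-row background.
* **Boundary coalitions.** `|z'| = 0` and `|z'| = M` have infinite kernel
  weight; they are enforced as *hard constraints* — `g(empty) = phi0` and
  `g(full) = f(x)` — rather than as large finite weights. The second
  constraint is eliminated algebraically
  (`phi_M = f(x) - phi0 - sum_{i<M} phi_i`), so **local accuracy holds by
  construction**, exactly, in both exact and sampled modes.
* **Exact vs sampled coalitions.** For `M <= enum_limit` (default 12, i.e.
  at most 4094 interior coalitions) all coalitions are enumerated and the
  solve is exact: on tree-ensemble models with `M` up to 8 it matches the
  brute-force Shapley oracle to better than 1e−6 per coordinate (the test
  suite checks every `M` in 2..8). Above the limit, coalition sizes are
  drawn from the distribution the kernel implies over sizes
  (`p(s) ∝ 1/(s(M−s))`), each sampled mask is emitted together with its
  complement, and repeat draws accumulate as integer multiplicities serving
  as regression weights (default budget 2048).
* **Degenerate systems.** The weighted normal equations are solved directly;
  a reciprocal condition number below tolerance raises a classed numerical
  error advising a larger budget, rather than returning garbage.
* **Multi-class handling.** One independent regression per class, all
  sharing the same coalition system and masked evaluations. Because class
  probabilities sum to 1 for every input, per-feature attributions sum to
  (numerically) zero across classes — a property the tests assert.
* **Probability vs log-odds scale.** Explanations default to the
  probability output (`link = "identity"`); `link = "logit"` explains
  log-odds instead. Published force-plot illustrations in this literature
  sometimes show outputs outside [0, 1], indicating a margin/log-odds scale;
  both are supported, and no instance-specific published value is treated
  as reproducible.

The **brute-force oracle** (`exact_shapley_oracle`, `M <= 10`) computes
`phi_i` from the defining average-marginal-contribution sum over all `2^M`
subsets, using the same masked evaluations. It is deliberately independent
of the regression path — same `v(S)`, different estimator — which is what
makes the agreement test meaningful.

## Summary- and force-plot data

`shap_summarize()` ranks features by mean absolute Shapley value over the
explained instances (the standard summary-plot ordering; ties break by
original feature order for determinism) and retains a per-instance
(feature value, attribution) scatter for the top `top_k` features (default
10). The number of instances explained is config-bound (default 200, a
seeded subsample) because Kernel SHAP cost is linear in instances.
`force_decompose()` splits one explanation's attributions by sign around the
base value and re-verifies additivity. Both serialize losslessly to
JSON/CSV; PNG rendering is a convenience, not part of any tested contract.

## The synthetic generator

`synthetic_spec()` emulates the *structure* of the public CTG table: the
1655/295/176 N/S/P imbalance, 21 continuous features, and a small set of
driver features whose class-conditional means shift in the clinically
reported directions — abnormal states raise ASTV, ALTV and DP and lower AC
and the histogram Mean. Features are unit-variance Gaussians (the generator
works on the post-normalization scale; absolute units of the real table
carry no information once z-scored). Default shifts, in standard deviations:

| feature | Suspicious | Pathologic |
|---|---|---|
| ASTV | +1.4 | +3.0 |
| ALTV | +1.2 | +1.4 |
| AC | −1.2 | −1.6 |
| Mean | −0.8 | −1.2 |
| DP | +0.2 | +1.2 |

The effect profile was calibrated once, at design time, against two
properties the generator is required to have: (i) the data are learnable —
a 200-tree bagged ensemble's 5-fold accuracy exceeds the majority-class
rate (0.7785) by at least 0.10 at the default sizes; and (ii) the primary
abnormal driver is recoverable — ASTV, the dominant pathologic signal,
tops the pathologic class's mean-|SHAP| ranking in seeded runs. The second
property pins the relative magnitudes: a profile giving DP a pathologic
shift close to ASTV's makes DP (the only P-specific signal) outrank ASTV in
P-class attributions, because ASTV's similar S and P shifts separate normal
from abnormal rather than pathologic from the rest.

What the generator does **not** emulate — and hence what passing tests on it
do not show about real data: feature-feature correlations (real histogram
statistics are strongly collinear), skewed and zero-inflated marginals
(DS/DP are rare-event counts), label noise from inter-observer disagreement,
and any nonlinear class boundary. Synthetic results demonstrate the
machinery (leak-free stacking, correct attribution), not clinical
performance; real-data performance must be measured on the real table.

A 2-class, 26-feature variant (`synthetic_private_spec()`) emulates a
hospital-style normal/abnormal table in which low AC, short acceleration
duration and low short-term variability drive the abnormal class; it is
synthetic stand-in plumbing, not a reproduction of any private cohort.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run on generated data scaled for a
single CPU: cross-validation demonstrations use 710 instances (550/100/60)
for the 10-fold protocol and 400 (300/60/40) for the 4-strategy comparison;
SHAP/oracle agreement uses `M` in 2..8 with small backgrounds (5–8 rows);
driver-recovery runs explain 15 instances per run with a 300-coalition
budget over a 20-row background. These sizes were chosen so each
demonstration remains a matter of seconds to a few minutes; the statistical
properties they exercise do not depend on scale.

## Known limitations

* Kernel SHAP cost grows as (coalitions × background rows × instances);
  explaining thousands of instances with a large background is expensive by
  construction. Tree-specific fast attribution (Tree SHAP) is out of scope.
* The sampled-coalition estimator is unbiased in the limit but noisy at
  small budgets; the shipped convergence test quantifies this on one model
  family only.
* The network meta learner's training is seeded but floating-point
  reduction order can differ across BLAS builds; cross-platform
  reproducibility is therefore "within 1e−6", not bit-exact, for stacked
  predictions (tree-only configurations are bit-exact).
* No ROC/AUC, calibration assessment or significance testing is provided.
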