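---
title: "Bounded validation of small-sample sulcal classifiers: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded validation of small-sample sulcal classifiers: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulcalclass)
```

This vignette records the statistical model behind the package, the meaning
and defaults of its parameters, what the synthetic-data generator does and
does not emulate, and the numerical and design decisions a user should know
before trusting (or modifying) the results.

## The problem

A case–control cohort of roughly a hundred subjects is described by a few
hundred sulcal morphometry features (length, mean depth, maximum depth per
labelled region). Any flexible classifier fit to such a table can reach
perfect resubstitution accuracy, and k-fold cross-validation — the standard
remedy — still has substantial variance at this sample size. The package's
central device is to complement cross-validation with *analytic upper bounds
on optimism*: quantities `μ` such that, with probability `1 − η`, the true
generalization accuracy is no more than `μ` below the measured
resubstitution accuracy.

## The bounds

### Concentration bound for linear rules

For a linear classifier in `d` dimensions fit on `n` points,

$$\mu(n, d, \eta) \;=\; \sqrt{\frac{\ln 2 + \ln \sum_{k=0}^{d-1}
\binom{n-1}{k} - \ln \eta}{2n}}.$$

The binomial sum counts linear dichotomies of `n` points in general position
in `d` dimensions; it is the growth function that replaces a union bound
over a finite hypothesis set. Properties worth internalizing:

- at `d = 1` the sum is 1 and the bound collapses to Hoeffding's
  $\sqrt{\ln(2/\eta)/(2n)}$;
- it is nondecreasing in `d` and decreasing in `n`;
- it is useless when `d` approaches `n` (at `n = 113, d = 113` it is 0.60 —
  more than the distance from perfect to chance accuracy), which is the
  honest message for full-feature linear models at this cohort size.

`concentration_bound()` evaluates the sum in log space
(`lchoose` + log-sum-exp), so it is exact to double precision at any `n`
that matters here; the test suite cross-checks small cases against exact
integer arithmetic. The function enforces `1 ≤ d ≤ n`. For `d > n` the
dichotomy count saturates at $2^{n-1}$, equal to its value at `d = n`, so
callers that face `d > n` (e.g. `compare_bounds()` on a full feature table)
cap `d` at `n` — an exact evaluation, not an approximation.

### PAC-Bayes dropout bound

For a trained network with squared parameter norm $\lVert\Theta\rVert^2$,
empirical loss $\hat L$, loss range $L_{\max}$, and dropout rate $\alpha$:

$$\mu \;=\; \min_{\lambda \in \Lambda}\; \frac{1}{1 - \frac{1}{2\lambda}}
\hat L + \frac{1}{1 - \frac{1}{2\lambda}} \cdot \frac{\lambda
L_{\max}}{n}\left(\frac{(1-\alpha)^{q}}{2}\lVert\Theta\rVert^{2} +
\ln\frac{k}{\eta}\right)$$

with $\Lambda$ a fixed grid of `k = 20` values on $(1/2, 10]$ (the union
bound over the grid is what puts `k` inside the logarithm). The dropout
exponent `q` on the $(1-\alpha)$ factor is configurable
(`dropout_exponent`, default 1): typeset versions of this bound are
ambiguous between $(1-\alpha)$ and $(1-\alpha)^2$, and the package makes
the choice explicit rather than silent. At $\alpha = 1$ the parameter-norm
term vanishes and only the grid penalty $\ln(k/\eta)$ remains, which the
tests assert.

### RUB validation

`rub_validate()` fits on all data, measures resubstitution metrics, and
subtracts the bound from balanced accuracy, sensitivity, and specificity
(AUC is reported uncorrected — the bound is stated for accuracy-type
quantities). The corrected value is **not floored at chance**: a corrected
balanced accuracy of 0.43 for a 14-dimensional rule at `n = 113` is the
method working as intended, telling you the guarantee is vacuous at that
dimensionality. By default `d` is the column count of the table handed to
the classifier; `d_reduce` inserts a PLS step and the bound is then
evaluated at the reduced dimension.

## The synthetic cohort generator

`simulate_table()` emulates the statistical signature of an automated
sulcal-morphometry extraction on a *curated* atlas:

- **Base features** are unit-variance Gaussians; planted effects shift the
  case-group mean by `delta` standard deviations *on that base scale*.
- **Depth correlation**: mean depth and maximum depth of a region share a
  latent factor giving correlation `depth_correlation` (default 0.7);
  length is independent.
- **Heavy tails**: a fraction (default 0.15) of features receive an
  additive lognormal contaminant, `rlnorm(n, 0, 1) − exp(0.5)` (mean zero,
  long right tail), identical in distribution across groups. This strength
  was chosen so Shapiro–Wilk rejects normality for contaminated columns
  with probability ≈ 0.99 at `n ≈ 114`, making the parametric/nonparametric
  routing meaningful; note a planted effect landing on a contaminated
  column is diluted after z-scoring — realistically so.
- **Misdetections** act at region level (all three measures NA at once)
  with a homogeneous per-(subject, region) probability.
- **Gross outliers** are injected per cell at 6–10 column SDs with random
  sign.

What the generator does **not** emulate: region-specific detection
stability. In real pipelines the attrition from a full candidate atlas
(~123 regions) down to a reliably detected subset (~49) is driven by some
sulci being intrinsically hard to label; a homogeneous misdetection rate
high enough to reproduce that attrition would also knock out planted-effect
regions at random. The shipped analysis therefore simulates the curated
49-region atlas with small residual rates, and the raw-cascade behavior is
exercised separately on constructed tables. Spatial covariance between
regions and demographic confounding are likewise out of scope.

`simulate_demographics()` rescales each group's covariates affinely so the
sample moments match the targets *exactly*, which makes printed summary
statistics reconstructible as test statistics (`t_from_moments()`,
`chi_square_2x2()`).

## Preprocessing cascade

`apply_exclusions()` applies, in order: (1) remove subjects with more than
`max_misdetected_regions` (default 18, strictly greater) misdetected
regions; (2) remove named regions (defaults: the two insulae, which
automated labelling handles poorly); (3) remove any region with residual NA
entries; (4) z-score columns using the **sample** standard deviation
(`n − 1` denominator — the choice matters for test oracles); (5) remove
subjects with any |z| > `outlier_sd` (default 6), **without**
re-normalizing afterwards, so the stored table's columns are not exactly
unit variance. Each removal is attributed to its rule in the returned
report. A numerical fact relevant to rule 5: a single extreme value in a
column of `n` can reach at most $|z| \approx (n-1)/\sqrt{n}$ after
z-scoring, so the 6-SD rule cannot fire at all below `n ≈ 38`.

## Feature selection

Two deliberately different routes:

- **Parametric route** (`univariate_selection()`): Shapiro–Wilk on each
  feature routes it to a pooled-variance two-sample t-test (both groups
  normal) or a Mann–Whitney U (otherwise, exact p where feasible, no
  continuity correction); features ranked by p-value.
- **Classifier route** (`sam_accuracies()` + `proportion_test()`): each
  feature's accuracy is the mean, over balanced subsamples of size twice
  the minority class, of a univariate linear discriminant's resubstitution
  accuracy *minus the d = 1 concentration bound* at that subsample size.
  The proportion test then takes $\pi_0$ = mean of these corrected
  accuracies, $l$ = number of features above $\pi_0$,
  $\sigma_0 = \sqrt{\pi_0(1-\pi_0)/l}$, and an upper-tail normal p-value
  for each feature. Using corrected accuracies for $\pi_0$ is the default
  (`corrected = TRUE`); the uncorrected variant is available since the
  quantity is defined either way.

## Dimensionality reduction and classifiers

PLS is implemented in-package with NIPALS, because two contracts matter
and are easiest to guarantee first-hand: a fixed **sign convention** (the
largest-magnitude entry of each weight vector is positive, so results are
reproducible across runs and platforms) and leakage-free **per-fold
refitting** (the rotation $W(P^\top W)^{-1}$ projects held-out samples; a
`leaky = TRUE` mode exists only to demonstrate the bias it creates). Tests
validate scores against an established PLS library and an independently
coded reference.

The linear SVM wraps `e1071::svm` (libsvm) and exposes the hyperplane
$(w, b)$, with orientation normalized so positive decision values mean the
case class. The MLP is hand-written (two ReLU hidden layers of 32 and 16
units, softmax output, class-weighted cross-entropy, Adam with batch size
1, 18 epochs, He initialization): no installed package offered
multi-hidden-layer networks with per-sample Adam control. Two numerical
guards are worth knowing: hidden biases start at 0.01 rather than 0, and if
an entire hidden layer is dead (all-zero activations on the training data)
the initialization is re-drawn deterministically (seed + 7919·attempt, up
to 10 attempts). Without these, narrow layers occasionally initialize dead
and the network is frozen at chance forever. Epoch shuffling is seeded
after the retry loop, so training order does not depend on the number of
re-draws.

## Validation harnesses

`stratified_folds()` assigns each class round-robin to folds with a
*continuous* offset across classes, so fold sizes differ by at most one
even when per-class counts are unbalanced. `stratified_kfold_validate()`
refits normalization-free steps (PLS, classifier) inside each fold.
`balanced_permutation_harness()` draws per-iteration seeds from a single
seeded stream, so iteration `i` is reproducible independently of how many
iterations run. `sweep_components()` and `sweep_sample_size()` produce the
dimensionality and sample-size curves; balanced subsampling caps the usable
`n` at twice the minority class.

## Explanations

`exact_shapley()` enumerates all $2^M$ coalitions (practical to `M = 12`),
substituting masked features by background means. `kernel_shap()` solves
the weighted least squares problem with Shapley kernel weights
$(M-1)/\!\left[\binom{M}{|z|}|z|(M-|z|)\right]$ and the efficiency
constraint eliminated analytically; when the requested coalition budget
reaches $2^M - 2$ it enumerates fully and reproduces the exact values,
which the tests assert at `M = 5`. `explain_local()` fits a ridge-stabilized
(`1e-6`) weighted linear surrogate in a Gaussian neighborhood. The shipped
analysis explains the selected-feature MLP rather than the full-feature
one: at `n = 113` the 138-feature network memorizes its training data and
generalizes at chance, and explaining a chance-level model explains noise.

## Problem sizes used in the tests

The test suite anchors closed-form values at cohort-scale sizes chosen as
this package's own reference points: bounds at `n = 112` with `d = 9` and
`d = 4` (0.3695 and 0.2675 at `η = 0.05`), a 2×2 sex table with chi-square
0.85, a pooled t of 1.93 from printed moments, and a 123-region raw table
whose cascade retains 49 regions and 113 of 116 subjects. Property tests
(bound monotonicity, PAC-Bayes grid limits, kernel-vs-exact Shapley
agreement, null calibration and planted-effect recovery of both selection
routes) run on smaller synthetic tables for speed.

## Limitations

- The bounds are for the *deviation of accuracy-type quantities*; AUC is
  reported without correction.
- The concentration bound assumes the `d`-dimensional representation is
  fixed before seeing labels; using it after label-aware selection
  understates optimism, which is why the shipped analysis selects features
  and evaluates bounds on the same data only in clearly labelled summary
  tables, while the cross-validation harness refits selection-free steps
  per fold.
- The generator's misdetection model is homogeneous; it cannot reproduce
  region-specific attrition (see above).
- The MLP is a minimal reference implementation (no early stopping, no
  learning-rate schedule); it is meant as a subject for the bounds and the
  explanation operators, not as a tuned clinical model.
- Kernel SHAP with background-mean substitution assumes feature
  independence in the masked positions, a known approximation shared with
  standard implementations.
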