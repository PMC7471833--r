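---
title: "Methods: cross-fold Shapley stability selection for multiscale expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-fold Shapley stability selection for multiscale expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapstab)
```

## The problem

Binary patient stratification from transcriptomic profiles — for example,
separating estrogen-receptor-positive from -negative breast tumors — is
usually approached by filtering tens of thousands of mRNA features with a
univariate statistic, ranking the survivors with a feature-selection
heuristic, and fitting a classifier to the top *n*. Two weaknesses of that
recipe motivate this package. First, a single feature type (mRNA *or*
microRNA) reflects only one layer of the underlying biology; concatenating
separately normalized feature blocks ("multiscale" features) can carry
complementary signal. Second, univariate filters with an arbitrary cut-off
admit features that have no stable relationship to the phenotype. shapstab
implements an alternative selector: model-based Shapley attributions,
aggregated across cross-validation folds, with a feature kept only when it
is *stably* among the most important ones.

## The selection procedure

Let $f$ be a fitted classifier over $M$ features, scoring an instance $x$
with its positive-class probability. The Shapley value of feature $i$ is
the average marginal contribution of $i$ over all feature coalitions $S$:

$$\phi_i(f, x) = \sum_{S \subseteq \{1..M\}\setminus\{i\}}
  \frac{|S|!\,(M-|S|-1)!}{M!}\,\bigl(f_x(S\cup\{i\}) - f_x(S)\bigr),$$

with the additive (efficiency) property
$f(x) = \phi_0 + \sum_i \phi_i(f,x)$, where $\phi_0 = f_x(\varnothing)$.

The selector runs a $K$-fold cross-validation ($K = 10$ by default):

1. partition the samples into $K$ class-stratified folds;
2. for fold $k$, fit the classifier on the fold's *training* portion and
   compute the Shapley matrix $S^k_{x,y}$ on that same training portion;
3. score every feature $y$ by the fold importance
   $\mathit{Ssub}^k_y = \sum_x |S^k_{x,y}|$ (absolute values, so opposing
   per-sample contributions cannot cancel);
4. binarize each fold at its top $k_{\mathrm{top}}$ importances
   (default 300);
5. sum the indicators across folds, $F_y = \sum_k \widetilde{S}^k_y$, and
   keep features with $F_y$ **strictly greater than** the threshold
   (default 5, i.e. at least 6 of 10 folds).

The held-out tenth of each fold plays no role in selection; attributions
are deliberately computed on the data the model was fitted to, as the
procedure is a measure of what the fitted models themselves rely on. The
strict inequality at the threshold is intentional and tested
($F_y = 5$ excluded, $F_y = 6$ included).

## Computing the Shapley values

The coalition value $f_x(S)$ is the **marginal (interventional)
expectation** over a fixed background sample: features outside $S$ are
replaced by background values and the model scores averaged. $f_x$ is
often described abstractly as a conditional expectation, which leaves the
estimator open; the marginal form is the standard tractable choice, and
it makes the exact oracle well defined ($f_x(\text{all}) = f(x)$,
$f_x(\varnothing) = $ mean score over the background). Attributions under
the alternative path-dependent tree convention would differ. The
explained output is the positive-class probability, a bounded score on
which the additive decomposition is easy to interpret.

Three interchangeable evaluators are provided and cross-checked:

* `exact_shapley()` — direct enumeration of all $2^M$ coalitions,
  capped at $M \le 15$. This is the oracle; the axioms (efficiency,
  dummy, symmetry, linearity) are asserted against it in the test suite.
* `estimate_shapley()` — Monte-Carlo permutation sampling. One random
  permutation yields one unbiased marginal-contribution draw per feature;
  the per-feature standard error is returned, and the estimator is tested
  to agree with the oracle within Monte-Carlo error.
* `tree_shapley()` — an exact evaluator for the built-in tree ensemble.
  For one tree and one background row, each root-to-leaf path constrains
  a small set of features to come from the instance ("must be in the
  coalition") or the background ("must be out"); the Shapley value of
  such a path game has a closed form, so summing over leaves gives the
  exact interventional attribution in time linear in the number of
  leaves. It equals `exact_shapley()` to machine precision on small
  problems (tested) and is what makes stability selection over thousands
  of features affordable.

The default background is a seeded subsample of up to 100 training rows.
In the acceptance-scale simulations the package uses 25 rows — a runtime
knob of the expectation estimate, not a statistical threshold; the
Shapley values remain exact for the ensemble *given* the background.

## The classifier

No CRAN random-forest implementation is available in the supported
environment, so the package ships its own randomized-tree ensemble
(`tree_ensemble()`): bagged CART trees, Gini impurity, a fresh random
feature subset of size $\lfloor\sqrt{p}\rfloor$ at every node, defaults of
100 trees, maximum depth 12, minimum split size 5. Fitting is
deterministic given the seed (each tree owns a counter-derived RNG
stream). An L2-regularized logistic regression (glmnet, fixed
$\lambda = 0.01$, no internal CV) is the second reference classifier. Any
other model can be plugged in through `classifier_spec(fit_fun = ...)`
provided it exposes positive-class probabilities.

## Preprocessing

* **Normalization** (`normalize_block()`): default $\log_2(x+1)$ followed
  by a per-feature z-score whose center and scale are fitted on training
  samples only and then applied to held-out samples — required for scale
  comparability when blocks are concatenated. The z-score uses the
  population-SD convention (divide by $n$) so small worked examples are
  exact; a sample-SD switch exists. Zero-variance features map to all-zero
  rows instead of being dropped, keeping indices stable.
* **Filtering** (`ttest_filter()`): per-feature two-sample Student's
  t-test (equal variance; Welch by flag) on training samples, retaining
  $p < 0.05$ by default. Features constant in both groups get $p = 1$.
* **Split** (`split_train_test()`): uniform random 80/20 by default,
  mirroring plain random selection; training size is
  $\lfloor n \cdot \text{fraction} \rfloor$, a convention that has to be
  picked explicitly because 80% of an odd cohort size is ambiguous. A
  stratified option preserves class proportions.
* **Combination** (`combine_blocks()`): row concatenation of separately
  normalized blocks; feature ids are prefixed `mRNA:`/`miRNA:` so the
  provenance of every selected feature is recoverable.

## Classical rankers

Five single-feature rankers are provided for the benchmark axis:
log2 fold change (signed, with directional top-$n/2$ extraction from the
up- and down-regulated ends; odd $n$ takes $\lceil n/2\rceil$ up),
OneR (single-rule training accuracy), ReliefF (range-normalized feature
differences to $k=10$ nearest hits and misses), information gain and gain
ratio (bits, on discretized values). Discretization is equal-frequency
with 10 bins; when a feature has no more distinct values than bins, each
distinct value becomes its own bin. Published descriptions of these
rankers rarely pin down discretization or ReliefF parameters, and legacy
toolkits differ among themselves; the defaults here are declared choices,
exposed as arguments, and the entropy rankers are verified against an
exhaustive contingency-table oracle rather than against any particular
legacy implementation. Fold change uses a
symmetric pseudocount of $10^{-6}\times$ the global mean expression, and
ranks on raw-scale values while the other four rankers consume
normalized values. Ties everywhere break by (weight descending, feature
id ascending) — reproducibility is preferred over fidelity to any
external tool's internal order.

## The synthetic stated world

`generate_dataset()` emulates the *shape* of a paired mRNA/miRNA tumor
cohort, not any particular cohort: a wide mRNA block and a narrow miRNA
block (defaults 2000 and 300 features — real cohorts carry tens of
thousands of mRNAs and hundreds of miRNAs after filtering; the defaults
keep the same width asymmetry at desk scale), log2-scale Gaussian
expression with feature-level baselines
$\mu_f \sim N(5, 2)$ and within-class SD 1, exponentiated to nonnegative,
right-skewed FPKM-like values. A planted subset of features (defaults 50
mRNA, 10 miRNA — fewer in the miRNA block, making it the weaker signal
carrier) receives a between-class mean shift of `effect_size` (default 2)
within-class SDs on the log scale, with the direction alternating
deterministically by index so directional fold-change extraction always
has both ends. The positive-class fraction defaults to 0.75 — a typical
receptor-positive majority; the original cohort's actual proportions are
unpublished, so this is a package default, not a reproduced value.

What a green test on this world does establish: the selector recovers
planted signal with high precision and stays near-empty under the null;
the multiscale model is at least as good as the weaker single-scale
model. What it does not establish: performance on real cohorts, where
inter-feature correlation, batch structure and annotation noise — none of
which the generator models — can change the picture.

## Numerical choices and edge cases

* Exact-oracle additivity tolerance $10^{-8}$; the estimator is judged at
  3 Monte-Carlo standard errors. Across several hundred simultaneous
  z-scores a handful of near-3 excursions are expected from multiplicity
  alone, so the equivalence tests allow at most 1% of comparisons beyond
  3 SE and none beyond 5 SE.
* MCC with a zero denominator is defined as 0; F1 with no positives
  anywhere defaults to 1 (vacuous perfection), configurable to 0.
* The "does not degrade" margin in the multiscale acceptance comparison
  is 0.05 MCC, fixed before measurement.
* A fold-change direction with fewer than $n/2$ features is backfilled
  from the other direction with a warning.
* Stability-selection fold partitions are class-stratified (the source
  procedure does not say; stratification prevents single-class folds,
  and a lone-class fold raises an informative error).
* One global seed drives named sub-streams (labels, generation, split,
  folds, per-fold fits, backgrounds, explainers), so stages can be re-run
  independently and no package function perturbs the caller's RNG state.

## Known limitations

* The exact enumeration oracle is exponential and capped at 15 features;
  beyond the cap only the permutation estimator (any model) or the tree
  evaluator (built-in ensemble) applies.
* The tree evaluator implements the *interventional* convention only; a
  path-dependent evaluator in the style of the original tree explainers
  would produce different attributions.
* The benchmark harness deliberately ships two reference classifiers
  rather than a zoo of legacy algorithms; the grid is an extension point,
  and replication of any external toolkit's internals is out of scope.
* The generator draws features independently; an optional block
  correlation structure is not implemented.
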