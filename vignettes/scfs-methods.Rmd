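---
title: "Feature scoring by standard deviation and cosine similarity: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature scoring by standard deviation and cosine similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfs)
```

## The problem

Gene-expression matrices typically have tens of thousands of features, a few
dozen samples, imbalanced classes, and — very often — no labels at all.
Selecting a small, non-redundant subset of informative genes before
classification improves both stability and generalization. This package
implements a family of *unsupervised* filters that need nothing but the
matrix itself.

## The model

Let $D \in \mathbb{R}^{m \times d}$ hold $m$ samples and $d$ features
$f_1,\dots,f_d$. Two quantities are attached to every feature:

**Discernibility** is the sample standard deviation,
$$
dis_i \;=\; \sqrt{\tfrac{1}{m-1}\sum_{j=1}^m\bigl(f_{ji}-\bar f_i\bigr)^2},
$$
the proxy for how well the feature can separate the (unknown) groups: a
feature that is near-constant across samples cannot distinguish anything.

**Independence** penalizes redundancy through the absolute cosine similarity
matrix $C$, $c_{ij} = |f_i \cdot f_j| / (\lVert f_i\rVert\,\lVert
f_j\rVert)$. Each feature is compared against the features that out-rank it
in discernibility: let
$c^*_i = \max_{k \,:\, dis_k > dis_i} c_{ik}$ be the strongest similarity
between $f_i$ and its "higher set". The single feature with the largest
discernibility has no higher set; it instead receives the *best*
independence its neighbourhood allows, using the minimum similarity to any
other feature. Three functional forms turn $c^*_i$ into an independence
value, giving the three selector variants:

| variant | form | range |
|---|---|---|
| SCEFS (exponential) | $ind_i = e^{-c^*_i}$ | $[e^{-1}, 1]$ |
| SCRFS (reciprocal) | $ind_i = 1/c^*_i$ | $[1, \infty)$ |
| SCAFS (anti-cosine) | $ind_i = 1 - c^*_i$ | $[0, 1]$ |

This construction is the density-peaks idea transplanted to feature space:
a feature is valuable when it varies a lot *and* is not a copy of an even
more variable feature.

**Score and selection.** Each feature is placed in a 2-D decision plot with
discernibility on x and independence on y; its score is the area of the
rectangle under its point, $score_i = dis_i \times ind_i$. The selected
subset is the top-$k$ by score — the isolated upper-right-corner points of
the plot. `decision_plot_coordinates()` exports both the $(dis, ind)$
scatter and the sorted score curve.

```{r toy}
toy <- generate_toy(seed = 1)
sel <- select_features(toy$x, k = 5, variant = "scefs")
sel$selected
toy$planted
```

### Numerical conventions

Choices the defining formulas leave open, fixed here once and for all:

* **Self-similarity is excluded** from every max/min set ($k \ne i$):
  including $c_{ii}=1$ would force the top feature's exponential
  independence to its floor, the opposite of the intended "maximal
  independence for the maximal-discernibility feature".
* **Ties in discernibility.** The argmax feature is the lowest-index one
  among tied maxima. Any other feature tied at the maximum compares against
  tied features of lower column index, so its reference set is never empty;
  below the maximum, the higher set is defined by *strict* inequality.
* **Reciprocal clamp.** $1/c$ is undefined at $c=0$ (orthogonal features);
  $c^*$ is clamped below at $\varepsilon = 10^{-12}$, so orthogonal
  features get very large but finite independence.
* **Zero-norm features** get $c_{ij} = 0$ by definition. They also have
  $dis = 0$, hence score 0 — they can never be selected before any varying
  feature.
* **Rank ties** are broken by ascending column index, making rankings
  deterministic across platforms.
* A constant feature under min-max normalization maps to all zeros
  (division by zero avoided; zero discernibility downstream is the correct
  semantics for a feature with no distinguishing power).

### Where normalization sits in the pipeline

Per-feature min-max rescaling, $f' = (f - \min f)/(\max f - \min f)$, is
part of the evaluation protocol because distance-based classifiers are
scale-sensitive. Its statistics are always fitted on the training fold and
applied, *unclipped*, to the test fold — anything else leaks test
information.

The selector itself, however, scores the **unnormalized** (imputed) data.
This is a deliberate design decision: discernibility is a standard
deviation, and min-max rescaling maps every feature to $[0,1]$, collapsing
the sd signal to the ratio sd/range — for Gaussian-like features that ratio
is nearly constant regardless of the original variance, and the planted
informative features in our own simulations become unrecoverable (recovery
drops from $\approx 5/5$ to $\approx 0.4/5$ planted features in the top 5).
Scoring raw data preserves the variance signal; rescaling is then applied
to the classifier inputs only. On real expression data, where features
differ in distributional shape and not only scale, both orders can work;
this package commits to the order that is also well-defined on simulated
Gaussian data.

Missing values are imputed before anything else (normalization and scoring
need complete columns). The default is the feature's global mean — the
selector must stay label-free — with a supervised intra-class-mean mode
available for the evaluation harness, falling back to the global mean for
(class, feature) cells with no observation.

## The evaluation protocol

`make_fold_plan()` reproduces stratified round-robin partitioning: per
repeat, each class's shuffled samples are dealt one at a time into the
folds (10 folds, 5 repeats by default), so per-class fold sizes differ by
at most one and small classes are spread over distinct folds rather than
concentrated. `run_cv()` then, for every repeat × fold:

1. imputes the training fold (global mean) and carries the training means
   to the test fold;
2. ranks features on the training fold **only**;
3. fits min-max statistics on the training fold, applies them to both;
4. trains the classifier on the top-$k$ features and evaluates accuracy,
   AUC (MAUC for $l > 2$), F2, sensitivity and specificity on the held-out
   fold.

Adapters are provided for a deterministic Euclidean KNN ($K = 5$; distance
ties broken by smallest training index, vote ties by the nearest supporting
neighbour; per-class decision value = fraction of the $K$ votes) and a
linear SVM via `e1071::svm()` with penalty $C = 20$. Means are reported
over all repeat-fold results; the quoted spread is the standard deviation
of the per-repeat means. `variant = "random"` gives the random-subset
baseline used in the no-leakage benchmark.

### Metrics

The F2-measure combines precision and negative predictive value
("~precision"),
$$
F2 = \frac{2\,p\,\widetilde p}{p + \widetilde p},
$$
so that — unlike the classical F-measure — a classifier that calls
everything positive scores 0 rather than respectably. With $l > 2$ classes
the problem is decomposed one-vs-one: for each of the $l(l-1)/2$ class
pairs the term $p_{ij}\widetilde p_{ij}/(p_{ij}+\widetilde p_{ij})$ is
computed over the test samples whose true class is $i$ or $j$, and summed
with weight $4/(l(l-1))$; at $l = 2$ this reduces exactly to the binary
form. Within a pair, "positive prediction" means predicted class $i$;
predictions of a third class count as negative predictions. All
zero-denominator ratios are defined as 0, which reproduces the
characteristic degenerate pattern Sen = 1, Spe = 0, F2 = 0 of an
all-positive classifier. Sensitivity and specificity aggregate over pairs
with the same weights. AUC is the rank-based (Mann–Whitney) estimator with
ties counted half; MAUC averages the pairwise one-vs-one AUCs in the
Hand–Till manner, skipping (and renormalizing over) pairs missing a class
in the test fold.

## Comparing algorithms across datasets

Given an $N$-datasets × $M$-algorithms performance matrix,
`friedman_rank_test()` computes the classical Friedman chi-square on
within-dataset average ranks ($df = M - 1$), and `nemenyi_cd()` the
post-hoc critical difference
$$
CD = q_\alpha \sqrt{\frac{M(M+1)}{6N}},
$$
above which two mean ranks differ significantly. $q_\alpha$ is the
Studentized-range quantile at infinite df divided by $\sqrt 2$, computed
from `qtukey()` rather than a hard-coded table (an explicit `q_alpha`
override is accepted; with the textbook value 3.219 for $M = 11$,
$N = 18$, the CD is 3.5587). The test requires a complete matrix: the
caller must exclude algorithms with missing datasets — silently dropping
cells would change every rank row.

```{r nemenyi}
nemenyi_cd(M = 11, N = 18, q_alpha = 3.219)$cd
```

## What the synthetic data does and does not emulate

`generate_toy()` draws two Gaussian classes (20 + 20 samples × 100
features by default) with `n_informative = 5` planted features whose class
means differ by `offset = 3` (centered, ±1.5) and whose standard deviation
(2) is twice the noise sd (1). Under the default `"block"` covariance the
features form co-expression modules: `max(n_informative, 5)` groups share
a latent factor with loading `sqrt(rho)`, `rho = 0.5`, and each planted
feature anchors one module. This mirrors a basic fact of transcriptomic
data — genes come in correlated modules, and differentially expressed
genes sit inside them — and it matters for the method itself: the
reciprocal independence of a feature with *no* strong neighbour among its
higher-discernibility set diverges, so in a fully independent-noise design
(available as `cov_structure = "diagonal"`) whichever noise feature tops
the noise variance range can outscore genuinely informative ones under
SCRFS. A redundancy-penalizing selector is only meaningful on data that
has redundancy structure.

`bootstrap_split()` reproduces the per-class bootstrap: the training set is
drawn with replacement (e.g. 13 + 15 from 20 + 20, giving 28 training
draws), the test set is the out-of-bag samples, so no sample identity
appears on both sides; a plain holdout scheme is also provided since the
bootstrap convention is not uniquely determined. `generate_multiclass()`
supports the one-vs-one metrics with imbalanced Gaussian classes on
equally spaced means.

What passing the simulation-based tests shows: the ranking recovers
variance-plus-redundancy structure planted exactly as the score model
assumes it. What it does not show: robustness to heavy tails, batch
effects, dropout or outlier samples, none of which the generator emulates
— conclusions about real microarray or single-cell data need real data.

## Problem sizes and runtime

Scoring is $O(md + d^2)$ time and $O(d^2)$ memory, dominated by the
similarity matrix (`crossprod`). The package's own test and verification
runs use desk-scale sizes chosen to exercise every code path: oracle
comparisons up to $30 \times 60$, recovery and cross-validation studies on
$40 \times 100$ toys with 100 and 20 replicates respectively, and a
$d = 500$ vs $d = 1000$ timing probe for the quadratic growth contract.
A full 5×10-fold evaluation on a 60-sample, 20k-feature expression matrix
is minutes of work on one core.

## Known limitations

* Discernibility is label-free variance: a feature with large
  class-unrelated variance (a batch effect, say) scores high. That is
  inherent to the unsupervised premise.
* The reciprocal variant is unbounded and sensitive to near-orthogonal
  features (see above); the exponential and anti-cosine variants are
  bounded and better behaved — and induce the same ordering among features
  of equal discernibility.
* `suggest_k()` (largest relative gap on the score curve) is a pragmatic
  extension for picking the subset size; the core method takes `k` as an
  input, and the automatic rule should be treated as a starting point.
* The Friedman/Nemenyi module requires a complete performance matrix and
  implements no other post-hoc corrections.
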