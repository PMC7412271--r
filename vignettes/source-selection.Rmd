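---
title: "Selecting relevant information sources with an lp-norm MKL-SVM and local scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting relevant information sources with an lp-norm MKL-SVM and local scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mklselect)
```

## The problem

In multimodal classification problems the features arrive in named blocks —
*information sources* — that share one physical origin: the wavelet
statistics of one EEG electrode, the radiomic descriptors of one MRI
sequence. Acquiring and processing every source is costly, so the practical
question is which few sources actually carry the discriminative signal.
Feature-selection methods answer a different question: they score columns
one at a time, so a source can survive through a single stray feature while
its block structure is ignored.

`mklselect` treats the source as the unit of selection. Each source $m$ gets
its own Gaussian kernel $K_m$, computed only from that source's feature
block, and a support vector machine is trained on the convex combination

$$K_\eta(x_i, x_j) = \sum_{m=1}^{P} \eta_m K_m(x_i^m, x_j^m),$$

with the kernel weights $\eta$ learned jointly with the SVM under an
$\ell_p$-norm constraint. Under $\ell_1$ ($\sum_m \eta_m = 1$,
$\eta_m \ge 0$, the simplex) the solution is sparse: uninformative sources
are driven to zero weight, and the trained $\eta$ is a directly
interpretable relevance measure. $\ell_2$ yields a denser but still ordered
weighting.

## Locally scaled Gaussian kernels

A single global bandwidth $\sigma$ is a notoriously touchy parameter of the
Gaussian kernel. Local scaling replaces it with one bandwidth per sample,

$$\sigma_i = d(x_i, x_{(K)}),$$

the Euclidean distance from $x_i$ to its $K$-th nearest neighbour, and the
kernel becomes

$$K(x_i, x_j) = \exp\!\left(-\frac{\lVert x_i - x_j\rVert^2}{2\,\sigma_i \sigma_j}\right).$$

The continuous search over $\sigma$ collapses to a search over the integer
$K \in \{1, \dots, N-1\}$. Two implementation decisions matter here:

* **Bandwidths are per source.** Each kernel $K_m$ sees only source $m$'s
  block, so $\sigma_i$ is computed inside that block, giving each source its
  own bandwidth vector. A single shared $K$ is used across sources, matching
  its treatment as one tunable parameter.
* **Self-exclusion and the floor.** During training, sample $i$'s own row is
  excluded from its neighbour search. Every bandwidth is floored at
  $\varepsilon = 10^{-12}$ so duplicated rows can never produce a zero
  bandwidth.

The locally scaled kernel is not guaranteed positive semi-definite. Before
each SVM solve the combined training Gram is checked: if its minimum
eigenvalue falls below $-10^{-8}$ times the largest eigenvalue magnitude,
the negative spectrum is clipped to zero and a warning is emitted; otherwise
the matrix passes through untouched. The per-source margin norms that drive
the weight update are computed on the unclipped per-source Grams.

## Bandwidths for unseen samples

Local scaling is defined on training data only, so prediction needs a rule
for assigning bandwidths to new samples. Three algorithms are provided
(`algorithm` in `mkl_config()`):

1. **Full training set.** The test sample's bandwidth is its distance to its
   $K$-th nearest training sample. Faithful, but the whole training set must
   be stored. The training set is used as-is: a training point coinciding
   with the test point counts at distance zero (the floor catches the
   $K = 1$ case). A consequence worth knowing: on a test point that
   coincides with training sample $i$, the rule with neighbour index $K + 1$
   reproduces the training $\sigma_i$, because the coincident duplicate
   occupies rank 1.
2. **Nearest support vector.** The test sample inherits the stored training
   bandwidth of its nearest support vector; only support vectors are kept.
3. **Mean support-vector bandwidths.** Every non-support training sample is
   assigned to its nearest support vector; each support vector carries the
   arithmetic mean of its own bandwidth and those of its assigned samples,
   and test samples inherit that mean. This recycles the neighbourhood
   information of the discarded samples at the same storage cost as
   Algorithm 2. When every training sample is a support vector, Algorithms 2
   and 3 coincide exactly.

All nearest-neighbour ties break deterministically towards the lowest
index. In the kernel expansion
$f(x) = \sum_i \alpha_i y_i K_\eta(x_i, x) + b$ the training side of each
cross-kernel always uses the support vector's own training bandwidth — the
algorithm only governs the test-side bandwidth. This keeps prediction
consistent with the training Gram and makes the Algorithm 2/3 reduction
property exact.

## Training the weights

Training alternates two steps, starting from uniform $\ell_p$-normalized
weights:

1. solve the single-kernel SVM dual on the current combined (clipped) Gram;
2. update the weights with the closed form
   $\eta_m \propto \lVert w_m\rVert_2^{2/(p+1)}$, normalized so
   $\lVert \eta\rVert_p = 1$, where
   $\lVert w_m\rVert_2^2 = \eta_m^2 \sum_{i,j} \alpha_i \alpha_j y_i y_j K_m(x_i^m, x_j^m)$.

The loop stops when the max-abs change in $\eta$ drops below `eta_tol`
(default $10^{-4}$) or after `max_outer_iters` (default 100) alternations;
a final SVM solve then makes the stored dual coefficients consistent with
the converged weights. For $p = 1$ the closed form already lands on the
simplex, so no projection step exists. Support vectors are the samples with
$\alpha_i > 10^{-8}$.

The inner dual solve is delegated to kernlab's interior-point QP solver
(`ipop`) on the precomputed Gram; the solver tolerance $\tau$ maps to its
significant-figure precision, and the bias is recovered from the KKT
conditions (mean over free support vectors, bound midpoint as fallback).
During development we found that SMO-style solvers can terminate prematurely
on spectrally clipped locally scaled Grams, under-reporting the dual optimum
by several units on small instances; the interior-point route is accurate to
the requested precision and is deterministic, which the test suite relies
on. The optimal weights minimize the optimal dual value $J(\eta)$ over the
$\ell_p$ ball (the dual is maximized over $\alpha$ *inside* $J$), and the
test suite checks the trained $\eta$ against a brute-force grid search of
$J$ over the simplex on small two-source instances.

## From weights to selections

`rank_sources()` orders sources by descending $\eta$ (ties keep manifest
order). `elimination_curve()` removes sources from least to most relevant
and re-scores the test set at every subset size. Its default `reweight` mode
renormalizes the retained weights to the model's $\ell_p$ ball and re-uses
the stored dual coefficients — prediction-stage reduction with no
retraining; `retrain` mode refits the full MKL on each retained subset.
Both are exposed because either protocol is defensible; they answer
slightly different questions (how much the *trained* model relies on the
sources, versus how well the *method* does with fewer sources).
`select_minimal()` picks the smallest subset size whose accuracy ties the
curve maximum. `aggregate_relevance()` combines weights across runs (e.g.
subjects), weighting each run by its accuracy and normalizing the result to
sum 100 — the scale is this package's own convention.

Performance is reported as accuracy, sensitivity, specificity (class +1 is
positive) and their geometric mean, all in percent; the geometric mean is
the tuning objective because it is robust to class imbalance. Ratios with
an empty denominator are reported as 0 with a `degenerate` flag rather than
an error, so elimination curves survive pathological subsets. The reduction
rate $1 - \text{selected}/\text{total}$ summarizes how many sources a
selection discards.

## Hyperparameter tuning

`tune_mkl()` optimizes $(C, K, \tau)$ by global-best particle swarm
optimization against the stratified 10-fold cross-validated geometric mean.
The swarm defaults are 40 particles, cognitive and social coefficients of
1.1931, and 60 iterations with the inertia interpolated linearly from 1.1
down to 0.1 — the decreasing direction is the common convention and is
configurable. Velocities are clamped to half the box width per dimension;
positions are clamped to the bounds; the $K$ dimension is rounded to the
nearest integer at evaluation time. The default search box is
$C \in [10^{-2}, 10^3]$ and $\tau \in [10^{-6}, 10^{-1}]$, both log-scaled,
and $K \in \{1, \dots, \min(20, N_{\text{train}} - 1)\}$, which brackets the
classic local-scaling default $K = 7$. Everything is deterministic under
the PSO seed, including fold assignment.

## The Fisher-score baseline

For comparison with per-feature selection, `fisher_scores()` ranks
concatenated features by
$FS(f_i) = \sum_j n_j (\mu_{ij} - \mu_i)^2 \big/ \sum_j n_j s_{ij}^2$
(population variances; the convention is pinned by a hand-computed test
case), and `fisher_eliminate()` sweeps retained-feature counts from all
features down to one, keeping rank prefixes. Two protocols are built on it:

* **Feature selection, then source survival**: sweep all concatenated
  features; a source survives if it retains at least one feature at the
  accuracy-optimal count.
* **Source selection, then feature reduction**: run the MKL selection
  first, then Fisher-sweep only the retained sources' features; the
  stage-1 sources are kept fixed.

The evaluator inside both sweeps is the $P = 1$ case of the same locally
scaled Gaussian SVM, so the comparison never leaves the model family. A
zero-denominator Fisher score with positive numerator is $+\infty$ and
ranks first; ties break by column order.

## What the synthetic data does and does not show

`make_multisource()` generates the test bed: `informative_shift` sources
draw every feature from $N(\pm\delta/2, \text{noise\_sd}^2)$ by class
(default $\delta = 3$, sd 1); `informative_rings` sources place class $-1$
on an annulus of radius 1 and class $+1$ at radius 3 (radial sd 0.25) — not
linearly separable, which is exactly the case the locally scaled Gaussian
kernel exists for; `noise` sources are class-independent standard normal.
The recovery fixture used by the test suite has one shift source and one
rings source among six noise sources, $n = 200$, balanced classes. The two
informative sources are deliberately *non-redundant*: an $\ell_1$ penalty
is expected to sparsify away duplicated signals, so two copies of the same
shift would not both retain weight — a property of the method, not a flaw
of the test.

Passing these tests shows that the pipeline recovers planted block-level
structure under clean Gaussian noise. Real EEG or MRI feature tables have
correlated features, heavy tails, batch effects and label noise that the
generator does not emulate; results on the fixtures bound what the
implementation does, not what any clinical dataset will yield.

## Numerical choices and problem sizes

Collected here so they are easy to audit: bandwidth floor $10^{-12}$;
PSD-clip threshold $-10^{-8}\cdot\lambda_{\max}$; support-vector threshold
$\alpha > 10^{-8}$; weight-convergence tolerance $10^{-4}$ with at most 100
alternations; weights below $10^{-8}$ print as exactly 0 in relevance
tables; the QP ridge is $10^{-10}$; stratified splits round per-class
training counts to the nearest integer and always leave at least one test
sample per class; standardization uses training-set population statistics
and maps zero-variance columns to zero. The test suite runs its
simulations at deliberately modest sizes — $n$ between 40 and 200, up to 8
sources, 20 seeds for the stochastic recovery check, 3–5 seeds for
statistical properties — chosen as the smallest sizes at which the checked
properties are stable.

## Limitations

Binary classification only, by construction of the base learner. Euclidean
distances only in the local-scaling step. The weighted sum is the only
kernel combination; base kernels are Gaussian only. Whether nearest-support-
vector lookups should use per-source or concatenated feature space is not
settled by theory; this implementation uses per-source lookups for
consistency with the per-source kernels.
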