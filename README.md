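# mklselect

Objective selection of relevant **information sources** in binary
classification. An information source is a named block of features sharing
one origin — an EEG electrode's wavelet statistics, one MRI sequence's
radiomic descriptors — and the practical question the package answers is:
*which few sources are actually needed to solve the task?*

## Who this is for

Researchers working with multimodal feature tables (EEG channel selection in
brain–computer interfaces, MRI sequence selection in radiology, any setting
where acquisition cost scales with the number of modalities) who want a
source-level relevance ranking that falls out of a trained classifier
instead of per-feature heuristics that ignore block structure.

## The method

Each source *m* is represented by its own Gaussian kernel, fused as a
weighted sum

    K_eta(x_i, x_j) = sum_m eta_m * K_m(x_i^m, x_j^m),

and an SVM is trained on the combination while the weights eta are learned
under an lp-norm constraint (multiple kernel learning). Under l1 the weights
live on the simplex and the solution is sparse: uninformative sources get
weight zero, and the trained eta ranks the sources by relevance. The kernel
bandwidths are set per sample by **local scaling** — sigma_i is the distance
from sample i to its K-th nearest neighbour within the source's own feature
block:

    K(x_i, x_j) = exp( -||x_i - x_j||^2 / (2 * sigma_i * sigma_j) ),

which turns the continuous bandwidth search into a search over one integer
K. Three algorithms assign bandwidths to unseen samples at prediction time
(full training set / nearest support vector / mean support-vector
bandwidths). (C, K, tau) are tuned by particle swarm optimization against a
10-fold cross-validated geometric mean of sensitivity and specificity, and
sources are eliminated from least to most relevant to find the minimal
subset. A Fisher-score feature-selection baseline with two comparison
protocols is included. See the vignette in `vignettes/source-selection.Rmd`
for the full model description and the package's design decisions.

## Worked example

```r
library(mklselect)

spec <- synth_spec(200, list(
  list(name = "electrode_A", n_features = 4, kind = "informative_shift", effect = 3),
  list(name = "electrode_B", n_features = 4, kind = "informative_rings"),
  list(name = "electrode_C", n_features = 4, kind = "noise"),
  list(name = "electrode_D", n_features = 4, kind = "noise")
), seed = 42)
ds <- make_multisource(spec)

parts <- split_dataset(ds, split_spec(seed = 42))          # stratified 80/20
std <- standardize(parts$train, list(parts$test))          # train stats only

fit <- mkl_train(std$train, mkl_config(C = 1, p = 1, K = 7, algorithm = 2))
fit
#> mkl_model: 4 source(s), 138 support vectors of 160 training samples
#>   penalty: l1-norm | C=1 K=7 tau=0.001 | prediction algorithm 2
#>   converged in 37 outer iteration(s): yes
#>   kernel weights (eta):
#>     electrode_A  0.8315
#>     electrode_B  0.1683
#>     electrode_C  0.0001
#>     electrode_D  0.0000

score(parts$test$labels, mkl_predict(fit, std$others[[1]]))
#> performance_report: acc 100.00% | geo-mean 100.00% | sens 100.00% | spec 100.00%
#>   confusion: TP=20 TN=20 FP=0 FN=0

curve <- elimination_curve(fit, std$others[[1]])
select_minimal(curve)$sources
#> [1] "electrode_A"
```

The two planted informative sources (a class-conditional mean shift and a
non-linearly-separable ring structure) take ~83% and ~17% of the l1 weight;
the two pure-noise sources collapse to zero, and the elimination curve shows
the task is solved with a single source (reduction rate 0.75). On real data
the weights are rarely this extreme — the fixture is clean by design.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mklselect` with subcommands `synth`, `train`, `curve`, `tune` and
`baseline`.

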