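# Shared fixtures and independent brute-force oracles, built in code.

# Recovery fixture: two non-redundant informative sources (a location shift
# and a ring structure) among six pure-noise sources. Non-redundancy matters:
# the l1 penalty is expected to sparsify away duplicated signals, so two
# copies of the same shift would not both keep weight.
recovery_spec <- function(seed, n = 200L) {
  src <- c(
    list(list(name = "inf_shift", n_features = 4, kind = "informative_shift",
              effect = 3),
         list(name = "inf_rings", n_features = 4, kind = "informative_rings")),
    lapply(1:6, function(i) list(name = paste0("noise", i), n_features = 4,
                                 kind = "noise"))
  )
  synth_spec(n, src, seed = seed)
}

# Small two-source dataset (informative shift + noise) for fast MKL tests.
two_source_spec <- function(seed, n = 60L, delta = 3) {
  synth_spec(n, list(
    list(name = "signal", n_features = 3, kind = "informative_shift",
         effect = delta),
    list(name = "static", n_features = 3, kind = "noise")
  ), seed = seed)
}

# Split + leakage-free standardization in one step.
prepare_split <- function(ds, seed = 1L, train_fraction = 0.8) {
  parts <- split_dataset(ds, split_spec(train_fraction = train_fraction,
                                        seed = seed))
  std <- standardize(parts$train, list(parts$test))
  list(train = std$train, test = std$others[[1L]],
       test_labels = parts$test$labels)
}

# Brute-force local-scaling bandwidths: full pairwise distance matrix, sort
# each row explicitly. Independent of the package's partial-sort path.
brute_sigmas <- function(X, K, floor = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (j != i) d <- c(d, sqrt(sum((X[i, ] - X[j, ])^2)))
    }
    out[i] <- sort(d)[K]
  }
  pmax(out, floor)
}

# Brute-force Fisher scores: explicit per-class loops over samples.
brute_fisher <- function(X, y) {
  X <- as.matrix(X)
  classes <- unique(y)
  out <- numeric(ncol(X))
  for (i in seq_len(ncol(X))) {
    mu <- mean(X[, i])
    num <- den <- 0
    for (cl in classes) {
      v <- X[y == cl, i]
      nj <- length(v)
      num <- num + nj * (mean(v) - mu)^2
      den <- den + nj * mean((v - mean(v))^2)
    }
    out[i] <- if (den > 0) num / den else if (num > 0) Inf else 0
  }
  out
}

# Independent dual-optimum evaluator J(eta1) for a 2-source training set:
# combined clipped Gram, one interior-point QP per grid point, dual value
# computed from the recovered alpha. Used by the simplex grid-search oracle.
dual_value_curve <- function(ds, K, C, etas, sigf = 9) {
  sig <- lapply(ds$sources, compute_local_sigmas, K = K)
  grams <- lapply(seq_along(ds$sources), function(m)
    local_gaussian_gram(ds$sources[[m]], sig[[m]]))
  y <- ds$labels
  n <- length(y)
  vapply(etas, function(e1) {
    Kc <- suppressWarnings(clip_psd(combine_kernels(grams, c(e1, 1 - e1))))
    H <- (y %o% y) * Kc + diag(1e-10, n)
    sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, nrow = 1),
                         b = 0, r = 0, l = rep(0, n), u = rep(C, n),
                         sigf = sigf, maxiter = 200)
    a <- pmin(pmax(kernlab::primal(sol), 0), C)
    sum(a) - 0.5 * drop(crossprod(a * y, Kc %*% (a * y)))
  }, numeric(1))
}
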