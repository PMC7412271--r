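# Hyperparameter tuning: stratified cross-validated geometric mean and
# global-best particle swarm optimization of (C, K, tau).

#' Cross-validated geometric-mean objective
#'
#' Stratified K-fold cross-validation of the MKL-SVM pipeline on a dataset:
#' each fold-complement is standardized and trained, the held-out fold is
#' scored, and the mean geometric mean across folds is returned (in
#' percent). Fold assignment is deterministic under `seed`.
#'
#' @param ds a `multisource_dataset` (typically the training split).
#' @param config an [mkl_config()].
#' @param folds number of folds (default 10); every class must have at
#'   least `folds` samples.
#' @param seed integer seed for the fold assignment.
#' @return Mean geometric mean across folds, in `[0, 100]`.
#' @export
cv_geo_mean <- function(ds, config = mkl_config(), folds = 10L, seed = 1L) {
  stopifnot(inherits(ds, "multisource_dataset"))
  if (!is_count(folds) || folds < 2L)
    mkl_stop("fold", "folds must be an integer of at least 2")
  y <- ds$labels
  for (cl in c(-1, 1))
    if (sum(y == cl) < folds)
      mkl_stop("fold", sprintf("class %+d has fewer samples than folds", cl))
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cl in c(-1, 1)) {
      members <- sample(which(y == cl))
      fold_of[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  gms <- vapply(seq_len(folds), function(f) {
    tr_idx <- which(fold_of != f)
    te_idx <- which(fold_of == f)
    tr <- subset_samples(ds, tr_idx)
    te <- subset_samples(ds, te_idx)
    std <- standardize(tr, list(te))
    cfg <- config
    if (cfg$K >= length(tr_idx)) cfg$K <- length(tr_idx) - 1L
    fit <- mkl_train(std$train, cfg)
    score(te$labels, mkl_predict(fit, std$others[[1L]]))$geo_mean
  }, numeric(1))
  mean(gms)
}

#' Particle swarm optimization configuration
#'
#' Defaults follow the global-best PSO settings used throughout the bundled
#' pipelines: 40 particles, cognitive and social coefficients 1.1931, a
#' linearly decreasing inertia from 1.1 to 0.1, and 60 iterations.
#'
#' @param n_particles swarm size (at least 2).
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param inertia length-2 vector `(start, end)` of the linear inertia
#'   schedule, within `[0.1, 1.1]`.
#' @param max_iters number of iterations.
#' @param seed integer seed.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 40L, c1 = 1.1931, c2 = 1.1931,
                       inertia = c(1.1, 0.1), max_iters = 60L, seed = 1L) {
  if (!is_count(n_particles) || n_particles < 2L)
    mkl_stop("config", "n_particles must be an integer of at least 2")
  if (length(inertia) != 2L || any(inertia < 0.1 - 1e-12) || any(inertia > 1.1 + 1e-12))
    mkl_stop("config", "inertia must be a (start, end) pair within [0.1, 1.1]")
  if (!is_count(max_iters) || max_iters < 1L)
    mkl_stop("config", "max_iters must be a positive integer")
  structure(list(n_particles = as.integer(n_particles), c1 = c1, c2 = c2,
                 inertia = inertia, max_iters = as.integer(max_iters),
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' A box-constrained search dimension for [pso_optimize()]
#'
#' @param lower,upper bounds (inclusive); `lower == upper` collapses the
#'   dimension to a constant.
#' @param integer round the value to the nearest integer at evaluation time
#'   (used for the neighbour index K)?
#' @param log search on a log10 scale (used for C and tau)?
#' @return A list describing the dimension.
#' @export
pso_dim <- function(lower, upper, integer = FALSE, log = FALSE) {
  if (!is_scalar_num(lower) || !is_scalar_num(upper) || lower > upper)
    mkl_stop("config", "bounds must satisfy lower <= upper")
  if (log && lower <= 0) mkl_stop("config", "log-scaled bounds must be positive")
  list(lower = lower, upper = upper, integer = isTRUE(integer), log = isTRUE(log))
}

#' Global-best particle swarm optimization
#'
#' Standard gbest PSO maximizing `objective` over a box: velocities are
#' updated with inertia (linearly interpolated across iterations), cognitive
#' and social pulls with uniform random factors, clamped to half the box
#' width per dimension; positions are clamped to the bounds. Integer
#' dimensions are rounded at evaluation time; log dimensions are searched in
#' log10 space. Non-finite objective values are treated as `-Inf`.
#'
#' @param objective function taking a named numeric parameter vector and
#'   returning a scalar to maximize.
#' @param bounds named list of [pso_dim()] dimensions.
#' @param config a [pso_config()].
#' @return An object of class `tuning_result` with `best_params`,
#'   `best_objective` and the per-iteration `trajectory` (non-decreasing).
#' @examples
#' res <- pso_optimize(function(p) -(p[["x"]] - 3)^2,
#'                     list(x = pso_dim(0, 10)),
#'                     pso_config(n_particles = 10, max_iters = 20, seed = 1))
#' res$best_params
#' @export
pso_optimize <- function(objective, bounds, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"))
  d <- length(bounds)
  nm <- names(bounds)
  if (is.null(nm) || any(!nzchar(nm)))
    mkl_stop("config", "bounds must be a named list")
  lo <- vapply(bounds, function(b) if (b$log) log10(b$lower) else b$lower, numeric(1))
  hi <- vapply(bounds, function(b) if (b$log) log10(b$upper) else b$upper, numeric(1))
  width <- hi - lo
  vmax <- pmax(width / 2, .Machine$double.eps)

  decode <- function(pos) {
    out <- pos
    for (j in seq_len(d)) {
      v <- pos[j]
      if (bounds[[j]]$log) v <- 10^v
      if (bounds[[j]]$integer) v <- round(v)
      out[j] <- v
    }
    stats::setNames(out, nm)
  }
  evaluate <- function(pos) {
    val <- tryCatch(objective(decode(pos)), error = function(e) NaN)
    if (!is.finite(val)) -Inf else val
  }

  with_seed(config$seed, {
    np <- config$n_particles
    pos <- matrix(stats::runif(np * d, min = rep(lo, each = np),
                               max = rep(hi, each = np)), nrow = np)
    vel <- matrix(0, nrow = np, ncol = d)
    pbest <- pos
    pbest_val <- apply(pos, 1L, evaluate)
    g <- which.max(pbest_val)
    gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
    trajectory <- numeric(config$max_iters)
    for (it in seq_len(config$max_iters)) {
      w <- if (config$max_iters == 1L) config$inertia[1L] else
        config$inertia[1L] + (config$inertia[2L] - config$inertia[1L]) *
          (it - 1) / (config$max_iters - 1)
      r1 <- matrix(stats::runif(np * d), nrow = np)
      r2 <- matrix(stats::runif(np * d), nrow = np)
      vel <- w * vel +
        config$c1 * r1 * (pbest - pos) +
        config$c2 * r2 * sweep(pos, 2L, gbest, function(x, g) g - x,
                               check.margin = FALSE)
      vel <- pmin(pmax(vel, matrix(-vmax, np, d, byrow = TRUE)),
                  matrix(vmax, np, d, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lo, np, d, byrow = TRUE)),
                  matrix(hi, np, d, byrow = TRUE))
      vals <- apply(pos, 1L, evaluate)
      improved <- vals > pbest_val
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_val[improved] <- vals[improved]
      g <- which.max(pbest_val)
      if (pbest_val[g] > gbest_val) { gbest <- pbest[g, ]; gbest_val <- pbest_val[g] }
      trajectory[it] <- gbest_val
    }
    structure(list(best_params = decode(gbest), best_objective = gbest_val,
                   trajectory = trajectory),
              class = "tuning_result")
  })
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("tuning_result: best objective", sprintf("%.4f", x$best_objective), "\n")
  cat("  params:", paste(sprintf("%s=%.6g", names(x$best_params), x$best_params),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Default (C, K, tau) search box for [tune_mkl()]
#'
#' C in `[1e-2, 1e3]` and tau in `[1e-6, 1e-1]`, both log-scaled; the
#' neighbour index K over the integers `1 .. min(20, N_train - 1)`, which
#' brackets the classic local-scaling default K = 7.
#'
#' @param n_train number of training samples.
#' @return A named list of [pso_dim()]s.
#' @export
default_mkl_bounds <- function(n_train) {
  list(C = pso_dim(1e-2, 1e3, log = TRUE),
       K = pso_dim(1, max(min(20, n_train - 1), 1), integer = TRUE),
       tau = pso_dim(1e-6, 1e-1, log = TRUE))
}

#' Tune (C, K, tau) by PSO against the cross-validated geometric mean
#'
#' @param ds training `multisource_dataset`.
#' @param base_config an [mkl_config()] providing the non-tuned fields
#'   (penalty order p, prediction algorithm, ...).
#' @param pso a [pso_config()].
#' @param bounds search box, by default [default_mkl_bounds()].
#' @param folds cross-validation folds for the objective.
#' @return A list with the `result` ([pso_optimize()] output) and `config`,
#'   an `mkl_config` carrying the tuned parameters, ready for
#'   [mkl_train()].
#' @export
tune_mkl <- function(ds, base_config = mkl_config(), pso = pso_config(),
                     bounds = default_mkl_bounds(n_samples(ds)), folds = 10L) {
  fold_seed <- pso$seed + 1L
  objective <- function(params) {
    cfg <- base_config
    cfg$C <- params[["C"]]
    cfg$K <- max(1L, as.integer(round(params[["K"]])))
    cfg$tau <- params[["tau"]]
    cv_geo_mean(ds, cfg, folds = folds, seed = fold_seed)
  }
  result <- pso_optimize(objective, bounds, pso)
  tuned <- base_config
  tuned$C <- result$best_params[["C"]]
  tuned$K <- max(1L, as.integer(round(result$best_params[["K"]])))
  tuned$tau <- result$best_params[["tau"]]
  list(result = result, config = tuned)
}
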