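# lp-norm multiple-kernel-learning SVM: alternating single-kernel SVM solves
# on the combined Gram and closed-form kernel-weight updates, plus prediction
# with algorithm-specific test bandwidths.

SV_ALPHA_THRESHOLD <- 1e-8

#' MKL-SVM configuration
#'
#' @param C SVM regularization parameter (positive).
#' @param p norm order of the kernel-weight penalty; `p = 1` gives the sparse
#'   simplex constraint (sum of weights 1, uninformative sources driven to
#'   zero weight), `p = 2` the Euclidean ball. Any `p >= 1` is accepted.
#' @param tau stopping tolerance of the inner SVM solver (positive).
#' @param K local-scaling neighbour index (integer, `1 <= K < N_train`).
#' @param algorithm prediction-stage bandwidth assignment algorithm: 1 (full
#'   training set), 2 (nearest support vector's bandwidth) or 3 (nearest
#'   support vector's mean bandwidth). See [assign_sigmas_alg1()].
#' @param max_outer_iters maximum number of alternations between the SVM
#'   solve and the weight update (default 100).
#' @param eta_tol convergence threshold on the max-abs change in the kernel
#'   weights (default 1e-4).
#' @param sigma_floor minimum local-scaling bandwidth.
#' @param seed integer seed recorded with the model (training itself is
#'   deterministic).
#' @return An object of class `mkl_config`.
#' @export
mkl_config <- function(C = 1, p = 1, tau = 1e-3, K = 7L, algorithm = 2L,
                       max_outer_iters = 100L, eta_tol = 1e-4,
                       sigma_floor = DEFAULT_SIGMA_FLOOR, seed = 1L) {
  if (!is_scalar_num(C) || C <= 0) mkl_stop("parameter", "C must be positive")
  if (!is_scalar_num(p) || p < 1) mkl_stop("parameter", "p must be >= 1")
  if (!is_scalar_num(tau) || tau <= 0) mkl_stop("parameter", "tau must be positive")
  if (!is_count(K) || K < 1) mkl_stop("parameter", "K must be a positive integer")
  if (!algorithm %in% 1:3) mkl_stop("parameter", "algorithm must be 1, 2 or 3")
  if (!is_count(max_outer_iters) || max_outer_iters < 1)
    mkl_stop("parameter", "max_outer_iters must be at least 1")
  structure(list(C = C, p = p, tau = tau, K = as.integer(K),
                 algorithm = as.integer(algorithm),
                 max_outer_iters = as.integer(max_outer_iters),
                 eta_tol = eta_tol, sigma_floor = sigma_floor,
                 seed = as.integer(seed)),
            class = "mkl_config")
}

#' Weighted sum of per-source Gram matrices
#'
#' @param gram_stack list of P Gram matrices of identical shape.
#' @param eta numeric weight vector of length P.
#' @return The elementwise weighted sum.
#' @export
combine_kernels <- function(gram_stack, eta) {
  if (length(gram_stack) != length(eta))
    mkl_stop("structural", "one weight per Gram matrix is required")
  dims <- lapply(gram_stack, dim)
  if (length(unique(dims)) != 1L)
    mkl_stop("structural", "all Gram matrices must share the same shape")
  out <- eta[1L] * gram_stack[[1L]]
  for (m in seq_along(gram_stack)[-1L]) out <- out + eta[m] * gram_stack[[m]]
  out
}

#' Per-source squared margin norms
#'
#' For each source m, `||w_m||^2 = eta_m^2 * sum_ij alpha_i alpha_j y_i y_j
#' K_m(x_i, x_j)`, the squared norm of that source's contribution to the
#' decision hyperplane. These drive the kernel-weight update. Tiny negative
#' values arising from spectral clipping are set to 0.
#'
#' @param eta current kernel weights (length P).
#' @param alpha dual coefficients (length N, in `[0, C]`).
#' @param labels training labels in \{-1, +1\} (length N).
#' @param gram_stack list of P training Gram matrices.
#' @return Numeric vector of length P, all entries `>= 0`.
#' @export
compute_wm_norms <- function(eta, alpha, labels, gram_stack) {
  ay <- alpha * labels
  w2 <- vapply(seq_along(gram_stack), function(m) {
    eta[m]^2 * drop(crossprod(ay, gram_stack[[m]] %*% ay))
  }, numeric(1))
  pmax(w2, 0)
}

#' Closed-form lp-norm kernel-weight update
#'
#' `eta_m` is proportional to `||w_m||^(2/(p+1))`, normalized so that the
#' lp-norm of the weight vector is exactly 1. For `p = 1` this reduces to
#' `eta_m = ||w_m|| / sum_h ||w_h||`, i.e. the simplex condition with no
#' extra projection step. Sources with zero margin norm receive weight 0.
#'
#' @param wm_norms squared margin norms from [compute_wm_norms()].
#' @param p norm order (`>= 1`).
#' @return Updated weight vector with `lp_norm(eta, p) == 1`.
#' @export
update_eta <- function(wm_norms, p) {
  if (any(wm_norms < 0)) mkl_stop("parameter", "squared norms must be >= 0")
  if (all(wm_norms == 0))
    mkl_stop("degenerate", "all margin norms are zero; the model is degenerate")
  num <- wm_norms^(1 / (p + 1))
  den <- sum(wm_norms^(p / (p + 1)))^(1 / p)
  num / den
}

# Inner single-kernel SVM dual solve on a precomputed Gram, delegated to
# kernlab's interior-point QP solver ipop (the SMO path in ksvm terminates
# prematurely on some clipped locally-scaled Grams, underestimating the dual
# optimum). tau maps to ipop's significant-figures stopping precision. The
# bias is recovered from the KKT conditions. Returns full-length alpha so
# that f(x) = sum_i alpha_i y_i K(x_i, x) + bias.
svm_solve <- function(Kmat, y, C, tau) {
  n <- length(y)
  H <- (y %o% y) * Kmat
  H <- H + diag(1e-10, n)   # tiny ridge keeps the QP strictly solvable
  sigf <- min(max(round(-log10(tau)) + 4, 4), 13)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, nrow = 1),
                       b = 0, r = 0, l = rep(0, n), u = rep(C, n),
                       sigf = sigf, maxiter = 200)
  alpha <- pmin(pmax(kernlab::primal(sol), 0), C)
  alpha_y <- alpha * y
  f0 <- drop(Kmat %*% alpha_y)
  # KKT: free SVs satisfy y_i (f0_i + b) = 1, i.e. b = y_i - f0_i; with no
  # free SVs, b lies between the bound-derived lower and upper limits.
  r <- y - f0
  free <- alpha > 1e-6 * C & alpha < (1 - 1e-6) * C
  bias <- if (any(free)) {
    mean(r[free])
  } else {
    lo <- r[(alpha <= 1e-6 * C & y == 1) | (alpha >= (1 - 1e-6) * C & y == -1)]
    hi <- r[(alpha <= 1e-6 * C & y == -1) | (alpha >= (1 - 1e-6) * C & y == 1)]
    (max(c(lo, -Inf)) + min(c(hi, Inf))) / 2
  }
  if (!is.finite(bias)) bias <- 0
  list(alpha = alpha, alpha_y = alpha_y, bias = bias,
       objective = sum(alpha) - 0.5 * drop(crossprod(alpha_y, Kmat %*% alpha_y)))
}

#' Train an lp-norm MKL-SVM over locally scaled Gaussian kernels
#'
#' Computes per-source local-scaling bandwidths and Gram matrices, then
#' alternates (a) a single-kernel SVM dual solve with tolerance `tau` on the
#' current combined Gram (clipped to the PSD cone when indefinite) and (b)
#' the closed-form weight update [update_eta()], starting from uniform
#' lp-normalized weights, until the max-abs weight change drops below
#' `eta_tol` or `max_outer_iters` is reached. A final SVM solve on the
#' converged combination makes the stored dual coefficients consistent with
#' the stored weights. The trained weights `eta` rank the sources by
#' relevance.
#'
#' @param train_ds a `multisource_dataset` (standardized features are
#'   recommended; see [standardize()]).
#' @param config an [mkl_config()]; `config$K` must be `< n_samples(train_ds)`.
#' @return An object of class `mkl_model` with dual coefficients `alpha`,
#'   `bias`, `sv_indices`, kernel weights `eta`, the per-source
#'   support-vector blocks and bandwidths (plain and mean), the full
#'   training blocks and bandwidths when `algorithm == 1`, convergence
#'   information, and the configuration.
#' @examples
#' spec <- synth_spec(60, list(
#'   list(name = "signal", n_features = 3, kind = "informative_shift", effect = 3),
#'   list(name = "static", n_features = 3, kind = "noise")
#' ), seed = 2)
#' ds <- make_multisource(spec)
#' fit <- mkl_train(ds, mkl_config(K = 5))
#' fit$eta   # relevance weights; "signal" should dominate
#' @export
mkl_train <- function(train_ds, config = mkl_config()) {
  stopifnot(inherits(train_ds, "multisource_dataset"),
            inherits(config, "mkl_config"))
  y <- train_ds$labels
  n <- n_samples(train_ds)
  P <- n_sources(train_ds)
  if (length(unique(y)) < 2L)
    mkl_stop("label", "training labels contain a single class")
  if (config$K >= n)
    mkl_stop("parameter", sprintf("K (%d) must be < number of training samples (%d)",
                                  config$K, n))
  sigmas <- lapply(train_ds$sources, compute_local_sigmas,
                   K = config$K, floor = config$sigma_floor)
  grams <- lapply(seq_len(P), function(m)
    local_gaussian_gram(train_ds$sources[[m]], sigmas[[m]]))
  names(grams) <- train_ds$source_names

  eta <- rep(1, P); eta <- eta / lp_norm(eta, config$p)
  iters <- 0L; converged <- FALSE
  sol <- NULL
  for (it in seq_len(config$max_outer_iters)) {
    iters <- it
    # warn about indefiniteness once per training run, not per iteration
    Kc <- clip_psd(combine_kernels(grams, eta), warn = it == 1L)
    sol <- svm_solve(Kc, y, config$C, config$tau)
    w2 <- compute_wm_norms(eta, sol$alpha, y, grams)
    if (all(w2 == 0))
      mkl_stop("degenerate", "all margin norms vanished during training")
    eta_new <- update_eta(w2, config$p)
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta <= config$eta_tol) { converged <- TRUE; break }
  }
  # Final solve so alpha matches the converged weights.
  Kc <- clip_psd(combine_kernels(grams, eta), warn = FALSE)
  sol <- svm_solve(Kc, y, config$C, config$tau)

  sv <- which(abs(sol$alpha) > SV_ALPHA_THRESHOLD)
  if (!length(sv)) mkl_stop("degenerate", "no support vectors found")
  sv_blocks <- lapply(train_ds$sources, function(X) X[sv, , drop = FALSE])
  sv_sigmas <- lapply(sigmas, function(s) s[sv])
  mean_sv_sigmas <- lapply(seq_len(P), function(m)
    compute_mean_sv_sigmas(train_ds$sources[[m]], sigmas[[m]], sv))
  names(mean_sv_sigmas) <- train_ds$source_names

  model <- list(
    format_version = 1L,
    source_names = train_ds$source_names,
    eta = stats::setNames(eta, train_ds$source_names),
    alpha = sol$alpha, alpha_y = sol$alpha_y, bias = sol$bias,
    sv_indices = sv,
    sv_labels = y[sv],
    sv_blocks = sv_blocks,
    sv_sigmas = sv_sigmas,
    mean_sv_sigmas = mean_sv_sigmas,
    train_blocks = if (config$algorithm == 1L) train_ds$sources else NULL,
    train_sigmas = if (config$algorithm == 1L) sigmas else NULL,
    n_train = n,
    dual_objective = sol$objective,
    iterations = iters, converged = converged,
    config = config
  )
  class(model) <- "mkl_model"
  model
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("mkl_model: %d source(s), %d support vectors of %d training samples\n",
              length(x$eta), length(x$sv_indices), x$n_train))
  cat(sprintf("  penalty: l%g-norm | C=%g K=%d tau=%g | prediction algorithm %d\n",
              x$config$p, x$config$C, x$config$K, x$config$tau,
              x$config$algorithm))
  cat(sprintf("  converged in %d outer iteration(s): %s\n", x$iterations,
              if (x$converged) "yes" else "no (max_outer_iters reached)"))
  eta <- sort(x$eta, decreasing = TRUE)
  cat("  kernel weights (eta):\n")
  for (nm in names(eta)) cat(sprintf("    %-12s %.4f\n", nm, eta[[nm]]))
  invisible(x)
}

# Test-sample bandwidths for every source under the model's algorithm.
assign_test_sigmas <- function(model, test_ds) {
  P <- length(model$source_names)
  lapply(seq_len(P), function(m) {
    Xt <- test_ds$sources[[m]]
    switch(model$config$algorithm,
      assign_sigmas_alg1(model$train_blocks[[m]], Xt, model$config$K,
                         model$config$sigma_floor),
      assign_sigmas_alg2(model$sv_blocks[[m]], model$sv_sigmas[[m]], Xt),
      assign_sigmas_alg3(model$sv_blocks[[m]], model$mean_sv_sigmas[[m]], Xt)
    )
  })
}

check_test_sources <- function(model, test_ds) {
  if (!identical(test_ds$source_names, model$source_names))
    mkl_stop("structural", "test sources must match training sources in name and order")
  for (m in seq_along(model$source_names))
    if (ncol(test_ds$sources[[m]]) != ncol(model$sv_blocks[[m]]))
      mkl_stop("structural", sprintf("source '%s' has %d features but was trained with %d",
                                     model$source_names[m],
                                     ncol(test_ds$sources[[m]]),
                                     ncol(model$sv_blocks[[m]])))
}

#' Decision values and predictions of a trained MKL-SVM
#'
#' Test bandwidths are assigned by the model's prediction algorithm, the
#' per-source cross-Grams between the stored support vectors and the test
#' samples are built with the locally scaled Gaussian kernel and combined
#' with the trained weights, and the decision value is the kernel expansion
#' `f(x) = sum_i alpha_i y_i K_eta(x_i, x) + b` over the support vectors.
#' `mkl_predict()` returns `sign(f)`, with the tie `f == 0` mapped to +1.
#'
#' @param model a trained [mkl_train()] model; for `eta` overrides see
#'   [elimination_curve()].
#' @param test_ds a `multisource_dataset` whose sources match the training
#'   sources in names, order and feature counts.
#' @param eta optional replacement weight vector (used by source-elimination
#'   re-weighting); defaults to the trained weights.
#' @return `decision_function()`: numeric decision values, one per test
#'   sample. `mkl_predict()`: labels in \{-1, +1\}.
#' @export
decision_function <- function(model, test_ds, eta = model$eta) {
  stopifnot(inherits(model, "mkl_model"))
  check_test_sources(model, test_ds)
  test_sigmas <- assign_test_sigmas(model, test_ds)
  cross <- lapply(seq_along(model$source_names), function(m)
    local_gaussian_gram(model$sv_blocks[[m]], model$sv_sigmas[[m]],
                        test_ds$sources[[m]], test_sigmas[[m]]))
  Kc <- combine_kernels(cross, as.numeric(eta))
  drop(crossprod(Kc, model$alpha_y[model$sv_indices])) + model$bias
}

#' @rdname decision_function
#' @export
mkl_predict <- function(model, test_ds, eta = model$eta) {
  f <- decision_function(model, test_ds, eta)
  ifelse(f >= 0, 1, -1)
}

#' Save / load a trained MKL-SVM model
#'
#' The archive is a single RDS file holding every model field plus a format
#' version tag; a round-tripped model reproduces identical predictions.
#'
#' @param model an `mkl_model`.
#' @param path file path for the archive.
#' @return `load_mkl_model()` returns the restored `mkl_model`.
#' @export
save_mkl_model <- function(model, path) {
  stopifnot(inherits(model, "mkl_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mkl_model
#' @export
load_mkl_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mkl_model") || is.null(model$format_version))
    mkl_stop("config", "not an mkl_model archive")
  model
}
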