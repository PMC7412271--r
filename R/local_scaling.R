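# Local-scaling bandwidths, locally scaled Gaussian Gram matrices, and the
# three prediction-stage bandwidth-assignment algorithms.

DEFAULT_SIGMA_FLOOR <- 1e-12

#' Per-sample bandwidths by local scaling
#'
#' The bandwidth of sample i is its Euclidean distance to its K-th nearest
#' *other* sample (self excluded), floored at `floor` so that later kernel
#' evaluations are always well defined. Small K captures local density;
#' large K approaches a global bandwidth.
#'
#' @param X numeric matrix, samples in rows.
#' @param K neighbour index, an integer with `1 <= K < nrow(X)`.
#' @param floor minimum bandwidth (default 1e-12).
#' @return Numeric vector of length `nrow(X)`, all entries `>= floor`.
#' @examples
#' compute_local_sigmas(matrix(c(0, 1, 3), ncol = 1), K = 1)  # 1, 1, 2
#' @export
compute_local_sigmas <- function(X, K, floor = DEFAULT_SIGMA_FLOOR) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is_count(K) || K < 1L || K >= n)
    mkl_stop("parameter", sprintf(
      "K must be an integer with 1 <= K < N (got K=%s, N=%d)", K, n))
  if (!is_scalar_num(floor) || floor <= 0)
    mkl_stop("parameter", "floor must be a positive number")
  d <- sqrt(cross_dist2(X, X))
  diag(d) <- Inf   # self excluded
  sig <- apply(d, 1L, function(r) sort(r, partial = K)[K])
  pmax(sig, floor)
}

#' Locally scaled Gaussian Gram matrix
#'
#' Entry (i, j) is `exp(-||a_i - b_j||^2 / (2 * sa_i * sb_j))`: a Gaussian
#' kernel in which the single global bandwidth is replaced by the geometric
#' pairing of the two samples' local-scaling bandwidths.
#'
#' @param Xa,Xb numeric matrices with matching feature counts (samples in
#'   rows); `Xb` defaults to `Xa`.
#' @param sigmas_a,sigmas_b positive bandwidth vectors, one entry per row of
#'   `Xa` / `Xb`.
#' @return A `nrow(Xa)` x `nrow(Xb)` matrix with entries in (0, 1]; symmetric
#'   with unit diagonal when `Xb` and `sigmas_b` equal `Xa` and `sigmas_a`.
#' @export
local_gaussian_gram <- function(Xa, sigmas_a, Xb = Xa, sigmas_b = sigmas_a) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb))
    mkl_stop("structural", "feature counts of the two blocks must match")
  if (length(sigmas_a) != nrow(Xa) || length(sigmas_b) != nrow(Xb))
    mkl_stop("parameter", "one bandwidth per sample is required")
  if (any(sigmas_a <= 0) || any(sigmas_b <= 0))
    mkl_stop("parameter", "bandwidths must be positive")
  d2 <- cross_dist2(Xa, Xb)
  exp(-d2 / (2 * outer(sigmas_a, sigmas_b)))
}

#' Prediction-stage bandwidth assignment
#'
#' Local scaling is defined on the training set; unseen samples need their
#' own bandwidths at prediction time. Three algorithms are provided:
#'
#' * **Algorithm 1** (`assign_sigmas_alg1`): the test sample's bandwidth is
#'   its distance to its K-th nearest *training* sample. Most faithful to the
#'   training rule but requires keeping the full training set. The training
#'   set is used as-is: a training point coinciding with the test point
#'   counts at distance 0 (the floor catches zero bandwidths).
#' * **Algorithm 2** (`assign_sigmas_alg2`): the test sample inherits the
#'   stored training bandwidth of its nearest support vector; only support
#'   vectors must be kept.
#' * **Algorithm 3** (`assign_sigmas_alg3`): as Algorithm 2, but each support
#'   vector carries a mean bandwidth (see [compute_mean_sv_sigmas()])
#'   summarizing the non-support training samples closest to it.
#'
#' Nearest-neighbour ties are broken by lowest index.
#'
#' @param train_X training feature matrix (one source's block).
#' @param test_X test feature matrix with the same feature count.
#' @param K neighbour index, `1 <= K <= nrow(train_X)`.
#' @param floor minimum bandwidth.
#' @return Numeric vector with one bandwidth per test sample.
#' @export
assign_sigmas_alg1 <- function(train_X, test_X, K, floor = DEFAULT_SIGMA_FLOOR) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  if (nrow(train_X) < 1L) mkl_stop("state", "empty training set")
  if (!is_count(K) || K < 1L || K > nrow(train_X))
    mkl_stop("parameter", "K must satisfy 1 <= K <= number of training samples")
  d <- sqrt(cross_dist2(test_X, train_X))
  sig <- apply(d, 1L, function(r) sort(r, partial = K)[K])
  pmax(sig, floor)
}

#' @rdname assign_sigmas_alg1
#' @param sv_X support-vector feature matrix (one source's block).
#' @param sv_sigmas stored training bandwidths of the support vectors.
#' @export
assign_sigmas_alg2 <- function(sv_X, sv_sigmas, test_X) {
  sv_X <- as.matrix(sv_X); test_X <- as.matrix(test_X)
  if (nrow(sv_X) < 1L) mkl_stop("state", "empty support-vector set")
  if (length(sv_sigmas) != nrow(sv_X))
    mkl_stop("parameter", "one bandwidth per support vector is required")
  d2 <- cross_dist2(test_X, sv_X)
  nearest <- apply(d2, 1L, which.min)   # which.min: ties -> lowest index
  sv_sigmas[nearest]
}

#' Mean support-vector bandwidths for Algorithm 3
#'
#' Every training sample that is not a support vector is assigned to its
#' nearest support vector (ties to the lowest index); each support vector's
#' mean bandwidth is the arithmetic mean of its own training bandwidth and
#' those of its assigned samples. Support vectors with no assigned samples
#' keep their own bandwidth, so when every training sample is a support
#' vector this reduces to the plain bandwidths (and Algorithm 3 to
#' Algorithm 2).
#'
#' @param train_X full training feature matrix (one source's block).
#' @param train_sigmas training bandwidths for all training samples.
#' @param sv_indices indices of the support vectors within `train_X`.
#' @return Numeric vector with one mean bandwidth per support vector.
#' @export
compute_mean_sv_sigmas <- function(train_X, train_sigmas, sv_indices) {
  train_X <- as.matrix(train_X)
  if (!length(sv_indices)) mkl_stop("state", "empty support-vector set")
  if (length(train_sigmas) != nrow(train_X))
    mkl_stop("parameter", "one bandwidth per training sample is required")
  sv_indices <- as.integer(sv_indices)
  rest <- setdiff(seq_len(nrow(train_X)), sv_indices)
  mean_sig <- train_sigmas[sv_indices]
  if (length(rest)) {
    d2 <- cross_dist2(train_X[rest, , drop = FALSE],
                      train_X[sv_indices, , drop = FALSE])
    nearest <- apply(d2, 1L, which.min)
    for (j in seq_along(sv_indices)) {
      assigned <- rest[nearest == j]
      if (length(assigned))
        mean_sig[j] <- mean(c(train_sigmas[sv_indices[j]],
                              train_sigmas[assigned]))
    }
  }
  mean_sig
}

#' @rdname assign_sigmas_alg1
#' @param mean_sv_sigmas mean bandwidths from [compute_mean_sv_sigmas()].
#' @export
assign_sigmas_alg3 <- function(sv_X, mean_sv_sigmas, test_X) {
  assign_sigmas_alg2(sv_X, mean_sv_sigmas, test_X)
}

#' Clip a symmetric kernel matrix to the positive semi-definite cone
#'
#' The locally scaled Gaussian kernel is not guaranteed positive
#' semi-definite. If the minimum eigenvalue of `K` falls below
#' `-tol * max(eigenvalue)`, negative eigenvalues are clipped to zero and a
#' warning is emitted; otherwise `K` passes through unchanged.
#'
#' @param K symmetric kernel matrix.
#' @param tol relative tolerance on the most negative eigenvalue.
#' @param warn emit a warning when clipping occurs?
#' @return A symmetric PSD matrix.
#' @export
clip_psd <- function(K, tol = 1e-8, warn = TRUE) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  lo <- min(e$values); hi <- max(abs(e$values))
  if (lo >= -tol * hi) return(K)
  if (warn) warning(sprintf(
    "kernel matrix is indefinite (min eigenvalue %.3e); clipping negative spectrum",
    lo), call. = FALSE)
  v <- pmax(e$values, 0)
  Kc <- e$vectors %*% (v * t(e$vectors))
  (Kc + t(Kc)) / 2
}
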