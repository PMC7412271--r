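# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish failure modes programmatically.
# class is one of: "structural", "label", "parameter", "state", "config",
# "split", "fold", "degenerate".
mkl_stop <- function(class, msg) {
  stop(structure(
    class = c(paste0("mklselect_", class, "_error"), "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

lp_norm <- function(x, p) {
  if (is.infinite(p)) return(max(abs(x)))
  sum(abs(x)^p)^(1 / p)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Squared Euclidean cross-distance matrix, rows of A vs rows of B.
cross_dist2 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
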