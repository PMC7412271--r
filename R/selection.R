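# Source ranking, sequential elimination curves, minimal-source selection and
# accuracy-weighted relevance aggregation across runs.

#' Rank sources by trained kernel weight
#'
#' @param model a trained [mkl_train()] model.
#' @return Character vector of source names in descending weight order; ties
#'   keep the original (manifest) source order.
#' @export
rank_sources <- function(model) {
  stopifnot(inherits(model, "mkl_model"))
  model$source_names[order(-model$eta, seq_along(model$eta))]
}

#' Sequential source-elimination curve
#'
#' Sources are eliminated from least to most relevant (by trained weight):
#' for every subset size n = P down to 1 the top-n ranked sources are kept
#' and the test set is re-scored. In `"reweight"` mode (default) the
#' retained weights are renormalized to the model's lp ball and prediction
#' reuses the stored dual coefficients — re-prediction without retraining.
#' In `"retrain"` mode the full MKL is refit on the retained sources.
#'
#' @param model a trained [mkl_train()] model.
#' @param test_ds test `multisource_dataset`.
#' @param mode `"reweight"` or `"retrain"`.
#' @param train_ds training dataset; required for `"retrain"`.
#' @return An object of class `elimination_curve`: the `ranking` and a
#'   data.frame `points` with one row per subset size (size, kept sources,
#'   reduction rate, performance measures).
#' @export
elimination_curve <- function(model, test_ds, mode = c("reweight", "retrain"),
                              train_ds = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "mkl_model"))
  if (mode == "retrain" && is.null(train_ds))
    mkl_stop("parameter", "retrain mode needs the training dataset")
  ranking <- rank_sources(model)
  P <- length(ranking)
  p <- model$config$p
  rows <- list(); reports <- list()
  for (n in P:1) {
    kept <- ranking[seq_len(n)]
    if (mode == "reweight") {
      eta_sub <- model$eta
      eta_sub[!model$source_names %in% kept] <- 0
      nrm <- lp_norm(eta_sub, p)
      if (nrm == 0)
        mkl_stop("degenerate", "all retained weights are zero; cannot renormalize")
      eta_sub <- eta_sub / nrm
      pred <- mkl_predict(model, test_ds, eta = eta_sub)
    } else {
      sub_fit <- mkl_train(subset_sources(train_ds, kept), model$config)
      pred <- mkl_predict(sub_fit, subset_sources(test_ds, kept))
    }
    rep <- score(test_ds$labels, pred)
    reports[[as.character(n)]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(
      n_sources = n,
      sources = paste(kept, collapse = ","),
      reduction_rate = reduction_rate(n, P),
      as.data.frame(rep)
    )
  }
  structure(list(ranking = ranking, mode = mode,
                 points = do.call(rbind, rows), reports = reports),
            class = "elimination_curve")
}

#' @export
print.elimination_curve <- function(x, ...) {
  cat(sprintf("elimination_curve (%s mode), ranking: %s\n",
              x$mode, paste(x$ranking, collapse = " > ")))
  df <- x$points
  df[c("accuracy", "sensitivity", "specificity", "geo_mean")] <-
    lapply(df[c("accuracy", "sensitivity", "specificity", "geo_mean")],
           function(v) sprintf("%.2f", v))
  print(df[c("n_sources", "reduction_rate", "accuracy", "geo_mean",
             "sensitivity", "specificity", "sources")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.elimination_curve <- function(x, ...) {
  graphics::plot(x$points$n_sources, x$points$accuracy, type = "b", pch = 19,
                 xlab = "number of sources kept", ylab = "accuracy (%)",
                 main = sprintf("Source elimination (%s)", x$mode), ...)
  invisible(x)
}

#' Minimal source subset attaining the curve's best accuracy
#'
#' @param curve an [elimination_curve()].
#' @return A list with `n` (the smallest subset size whose accuracy equals
#'   the maximum over the curve), `sources` (the kept sources), `report`
#'   (its [score()] report) and `reduction_rate`.
#' @export
select_minimal <- function(curve) {
  stopifnot(inherits(curve, "elimination_curve"))
  pts <- curve$points
  best_acc <- max(pts$accuracy)
  cand <- pts$n_sources[pts$accuracy == best_acc]
  n_star <- min(cand)
  row <- pts[pts$n_sources == n_star, ]
  list(n = n_star,
       sources = strsplit(row$sources, ",")[[1L]],
       report = curve$reports[[as.character(n_star)]],
       reduction_rate = row$reduction_rate)
}

#' Accuracy-weighted relevance aggregation across runs
#'
#' Aggregates the kernel weights of several runs (e.g. one per subject) into
#' a single relevance table: each source's score is proportional to the sum
#' over runs of (run accuracy x run weight), normalized to sum 100. Runs
#' with higher accuracy therefore count for more, and the output is
#' invariant to a common rescaling of all accuracies.
#'
#' @param runs list of runs, each a list with `eta` (named weight vector
#'   over a common source set) and `accuracy` (in (0, 100]).
#' @return An object of class `relevance_table`: a data.frame with `source`
#'   and `relevance` (descending), plus the contributing accuracies.
#' @export
aggregate_relevance <- function(runs) {
  if (!is.list(runs) || !length(runs))
    mkl_stop("parameter", "at least one run is required")
  nm <- names(runs[[1L]]$eta)
  if (is.null(nm)) nm <- paste0("S", seq_along(runs[[1L]]$eta))
  acc <- vapply(runs, function(r) r$accuracy, numeric(1))
  if (any(acc <= 0 | acc > 100))
    mkl_stop("parameter", "accuracies must lie in (0, 100]")
  tot <- numeric(length(nm)); names(tot) <- nm
  for (r in runs) {
    eta <- r$eta
    if (is.null(names(eta))) names(eta) <- nm
    tot[nm] <- tot[nm] + r$accuracy * as.numeric(eta[nm])
  }
  rel <- 100 * tot / sum(tot)
  ord <- order(-rel, seq_along(rel))
  structure(list(
    table = data.frame(source = nm[ord], relevance = as.numeric(rel[ord])),
    accuracies = acc
  ), class = "relevance_table")
}

#' @export
print.relevance_table <- function(x, ...) {
  cat(sprintf("relevance_table over %d run(s):\n", length(x$accuracies)))
  df <- x$table
  df$relevance <- sprintf("%.2f", df$relevance)
  print(df, row.names = FALSE)
  invisible(x)
}
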