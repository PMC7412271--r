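# Fisher-score feature ranking and the two comparison protocols:
# feature-selection-then-source-survival, and source-selection-then-
# feature-reduction.

#' Fisher scores for supervised feature ranking
#'
#' For feature i with overall mean `mu_i`, per-class sample counts `n_j`,
#' per-class means `mu_ij` and per-class *population* variances `s_ij^2`,
#' the Fisher score is
#' `FS(f_i) = sum_j n_j (mu_ij - mu_i)^2 / sum_j n_j s_ij^2`.
#' High scores mark features compact within each class and well separated
#' between classes. A zero denominator yields `+Inf` when the numerator is
#' positive (a perfectly compact, separated feature) and 0 otherwise;
#' infinite scores rank above all finite ones, ties by column order.
#'
#' @param X numeric feature matrix (samples in rows); typically the
#'   concatenated table from [as_concatenated()].
#' @param y label vector with at least two classes.
#' @param groups optional factor mapping each column of `X` to a source.
#' @return An object of class `fisher_ranking` with `scores` (per feature)
#'   and `order` (most to least relevant column indices).
#' @examples
#' X <- cbind(c(0, 2, 4, 6), c(1, 1, 1, 1))
#' fisher_scores(X, c(-1, -1, 1, 1))$scores   # 4, 0
#' @export
fisher_scores <- function(X, y, groups = NULL) {
  X <- as.matrix(X)
  classes <- unique(y)
  if (length(classes) < 2L)
    mkl_stop("label", "Fisher scores need at least two classes")
  mu <- colMeans(X)
  num <- den <- numeric(ncol(X))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    nj <- nrow(Xc)
    mu_j <- colMeans(Xc)
    var_j <- colMeans(sweep(Xc, 2L, mu_j)^2)   # population variance
    num <- num + nj * (mu_j - mu)^2
    den <- den + nj * var_j
  }
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  ord <- order(-scores, seq_along(scores))
  structure(list(scores = scores, order = ord,
                 feature_names = colnames(X), groups = groups),
            class = "fisher_ranking")
}

#' Backward feature elimination along a Fisher ranking
#'
#' Sweeps retained-feature counts from all features down to 1, keeping at
#' each step the top-k features of the ranking, and evaluates every prefix
#' with `evaluator`. The chosen count maximizes accuracy (ties broken
#' towards fewer features). When a group map is available, a source
#' "survives" if it retains at least one feature at the chosen count, and
#' the source-level [reduction_rate()] is reported.
#'
#' @param ranking a [fisher_scores()] ranking.
#' @param evaluator function mapping an integer vector of retained feature
#'   columns to a [score()] report.
#' @param groups factor mapping feature columns to sources; defaults to the
#'   ranking's.
#' @return A list with the sweep data.frame (`n_features`, accuracy, ...),
#'   `best_k`, `best_report`, the retained columns, `surviving_sources` and
#'   `source_reduction_rate` (the latter two `NULL` without a group map).
#' @export
fisher_eliminate <- function(ranking, evaluator, groups = ranking$groups) {
  stopifnot(inherits(ranking, "fisher_ranking"))
  D <- length(ranking$scores)
  rows <- list(); reports <- list()
  for (k in D:1) {
    cols <- ranking$order[seq_len(k)]
    rep <- evaluator(cols)
    reports[[k]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(n_features = k,
                                            as.data.frame(rep))
  }
  sweep_df <- do.call(rbind, rows)
  best_acc <- max(sweep_df$accuracy)
  best_k <- min(sweep_df$n_features[sweep_df$accuracy == best_acc])
  kept_cols <- ranking$order[seq_len(best_k)]
  out <- list(sweep = sweep_df, best_k = best_k,
              best_report = reports[[best_k]], kept_columns = kept_cols,
              surviving_sources = NULL, source_reduction_rate = NULL)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    surv <- levels(groups)[levels(groups) %in% unique(as.character(groups[kept_cols]))]
    out$surviving_sources <- surv
    out$source_reduction_rate <- reduction_rate(length(surv), nlevels(groups))
  }
  out
}

#' Single-source locally scaled Gaussian SVM evaluator
#'
#' Builds the evaluator used by the Fisher-sweep protocols: the retained
#' feature columns form one information source, the P = 1 case of the MKL
#' core is trained on the training table and scored on the test table, so
#' the baseline comparison stays inside the same model family.
#'
#' @param train_X,train_y training feature table and labels.
#' @param test_X,test_y test feature table and labels.
#' @param config an [mkl_config()] for the single-kernel fits.
#' @return A function mapping an integer column subset to a [score()]
#'   report.
#' @export
make_svm_evaluator <- function(train_X, train_y, test_X, test_y,
                               config = mkl_config()) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  function(cols) {
    tr <- multisource_dataset(list(F = train_X[, cols, drop = FALSE]), train_y)
    te <- multisource_dataset(list(F = test_X[, cols, drop = FALSE]), test_y)
    fit <- mkl_train(tr, config)
    score(test_y, mkl_predict(fit, te))
  }
}

#' Protocol 1: feature selection over all sources, then source survival
#'
#' Concatenates every source's features, ranks them by Fisher score, runs
#' the backward sweep with a single-kernel SVM evaluator, and reports which
#' sources survive (retain at least one feature) at the accuracy-optimal
#' feature count.
#'
#' @param train_ds,test_ds standardized train/test `multisource_dataset`s.
#' @param config an [mkl_config()] for the evaluator.
#' @return The [fisher_eliminate()] result.
#' @export
fisher_source_survival <- function(train_ds, test_ds, config = mkl_config()) {
  tr <- as_concatenated(train_ds)
  te <- as_concatenated(test_ds)
  ranking <- fisher_scores(tr$X, train_ds$labels, groups = tr$groups)
  evaluator <- make_svm_evaluator(tr$X, train_ds$labels, te$X, test_ds$labels,
                                  config)
  fisher_eliminate(ranking, evaluator)
}

#' Protocol 2: MKL source selection, then Fisher feature reduction
#'
#' Stage 1 trains the MKL-SVM, builds the source-elimination curve on the
#' test data and keeps the minimal source subset attaining the best
#' accuracy. Stage 2 concatenates the retained sources' features, ranks them
#' by Fisher score and runs the backward feature sweep; the sources selected
#' in stage 1 are kept fixed (they are not re-eliminated).
#'
#' @param train_ds,test_ds standardized train/test `multisource_dataset`s.
#' @param config an [mkl_config()].
#' @param mode elimination-curve mode for stage 1 (see
#'   [elimination_curve()]).
#' @return A list with `model`, `curve`, `selection` (stage 1),
#'   `fisher` (stage 2 sweep), `source_reduction_rate`,
#'   `feature_reduction` (retained / total feature counts) and
#'   `final_report`.
#' @export
select_then_reduce <- function(train_ds, test_ds, config = mkl_config(),
                               mode = "reweight") {
  model <- mkl_train(train_ds, config)
  curve <- elimination_curve(model, test_ds, mode = mode, train_ds = train_ds)
  sel <- select_minimal(curve)
  tr_sub <- subset_sources(train_ds, sel$sources)
  te_sub <- subset_sources(test_ds, sel$sources)
  trc <- as_concatenated(tr_sub)
  tec <- as_concatenated(te_sub)
  ranking <- fisher_scores(trc$X, tr_sub$labels, groups = trc$groups)
  evaluator <- make_svm_evaluator(trc$X, tr_sub$labels, tec$X, te_sub$labels,
                                  config)
  fsweep <- fisher_eliminate(ranking, evaluator)
  total_features <- sum(vapply(train_ds$sources, ncol, integer(1)))
  list(model = model, curve = curve, selection = sel, fisher = fsweep,
       source_reduction_rate = sel$reduction_rate,
       feature_reduction = list(kept = fsweep$best_k, total = total_features),
       final_report = fsweep$best_report)
}
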