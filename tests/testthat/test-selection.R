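fake_model <- function(eta) {
  nm <- names(eta)
  structure(list(eta = stats::setNames(as.numeric(eta), nm),
                 source_names = nm),
            class = "mkl_model")
}

fake_curve <- function(n_sources, accuracy) {
  pts <- data.frame(n_sources = n_sources, accuracy = accuracy,
                    sources = vapply(n_sources, function(n)
                      paste(paste0("S", seq_len(n)), collapse = ","),
                      character(1)),
                    reduction_rate = 1 - n_sources / max(n_sources))
  reports <- lapply(seq_along(n_sources), function(i) list(accuracy = accuracy[i]))
  names(reports) <- as.character(n_sources)
  structure(list(points = pts, reports = reports, mode = "reweight",
                 ranking = paste0("S", seq_len(max(n_sources)))),
            class = "elimination_curve")
}

test_that("sources are ranked by descending weight with stable ties", {
  m <- fake_model(c(A = 0.1, B = 0.7, C = 0.2))
  expect_equal(rank_sources(m), c("B", "C", "A"))
  expect_equal(rank_sources(fake_model(c(A = 1, B = 1, C = 1) / 3)),
               c("A", "B", "C"))
})

test_that("elimination curves re-weight the trained model consistently", {
  ds <- make_multisource(two_source_spec(seed = 12, n = 80))
  prep <- prepare_split(ds, seed = 12)
  fit <- mkl_train(prep$train, mkl_config(C = 1, p = 1, K = 5))
  full_rep <- score(prep$test_labels, mkl_predict(fit, prep$test))
  curve <- elimination_curve(fit, prep$test)

  expect_equal(nrow(curve$points), 2L)
  expect_equal(curve$points$reduction_rate, c(0, 0.5))
  # the n = P point is the untouched full model
  expect_equal(curve$points$accuracy[1], full_rep$accuracy)
  # the n = 1 point uses only the top source with weight exactly 1
  top <- curve$ranking[1]
  eta1 <- stats::setNames(as.numeric(fit$source_names == top), fit$source_names)
  expect_equal(curve$points$accuracy[2],
               score(prep$test_labels, mkl_predict(fit, prep$test, eta = eta1))$accuracy)

  # retrain mode refits on the kept sources
  curve_rt <- elimination_curve(fit, prep$test, mode = "retrain",
                                train_ds = prep$train)
  expect_equal(nrow(curve_rt$points), 2L)
  expect_equal(curve_rt$points$accuracy[1], full_rep$accuracy)
  expect_error(elimination_curve(fit, prep$test, mode = "retrain"),
               class = "mklselect_parameter_error")
})

test_that("identical sources with equal weights give a flat reweighted curve", {
  set.seed(31)
  X <- matrix(rnorm(80 * 2), 80, 2)
  X[, 1] <- X[, 1] + rep(c(-1.5, 1.5), each = 40)
  y <- rep(c(-1, 1), each = 40)
  ds <- multisource_dataset(list(A = X, B = X), y)
  prep <- prepare_split(ds, seed = 31)
  fit <- mkl_train(prep$train, mkl_config(C = 1, p = 1, K = 5))
  curve <- elimination_curve(fit, prep$test)
  expect_equal(curve$points$accuracy[1], curve$points$accuracy[2])
  expect_equal(curve$points$geo_mean[1], curve$points$geo_mean[2])
})

test_that("select_minimal picks the smallest subset at the curve maximum", {
  cv <- fake_curve(8:1, c(70, 70, 75, 80, 75, 80, 72, 70))
  # maxima at n = 5 and n = 3 -> smallest wins
  expect_equal(select_minimal(cv)$n, 3)
  flat <- fake_curve(4:1, rep(66, 4))
  expect_equal(select_minimal(flat)$n, 1)
  increasing <- fake_curve(4:1, c(60, 70, 80, 90))
  expect_equal(select_minimal(increasing)$n, 1)
})

test_that("relevance aggregation weights runs by accuracy and normalizes to 100", {
  single <- aggregate_relevance(list(list(eta = c(A = 0.7, B = 0.3),
                                          accuracy = 80)))
  expect_equal(single$table$relevance, c(70, 30))

  hand <- aggregate_relevance(list(
    list(eta = c(A = 1, B = 0), accuracy = 100),
    list(eta = c(A = 0, B = 1), accuracy = 50)))
  expect_equal(hand$table$relevance, c(200, 100) / 3, tolerance = 1e-10)

  # equal accuracies degenerate to the plain mean of the weights
  eq <- aggregate_relevance(list(
    list(eta = c(A = 0.9, B = 0.1), accuracy = 70),
    list(eta = c(A = 0.5, B = 0.5), accuracy = 70)))
  expect_equal(eq$table$relevance, c(70, 30))

  # invariant to common accuracy rescaling
  half <- aggregate_relevance(list(
    list(eta = c(A = 1, B = 0), accuracy = 50),
    list(eta = c(A = 0, B = 1), accuracy = 25)))
  expect_equal(half$table$relevance, hand$table$relevance)
  expect_equal(sum(half$table$relevance), 100, tolerance = 1e-6)

  expect_error(aggregate_relevance(list()), class = "mklselect_parameter_error")
})

test_that("dropping the top-ranked source does not improve training geo-mean on average", {
  diffs <- vapply(1:3, function(sd) {
    ds <- make_multisource(recovery_spec(seed = sd, n = 100))
    std <- standardize(ds)$train
    fit <- mkl_train(std, mkl_config(C = 1, p = 1, K = 7))
    full <- score(std$labels, mkl_predict(fit, std))$geo_mean
    drop_top <- fit$eta
    drop_top[rank_sources(fit)[1]] <- 0
    if (sum(drop_top) == 0) return(0)
    drop_top <- drop_top / sum(drop_top)
    full - score(std$labels, mkl_predict(fit, std, eta = drop_top))$geo_mean
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
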