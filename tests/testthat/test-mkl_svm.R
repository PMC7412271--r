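test_that("kernel combination and margin norms follow the weighted-sum algebra", {
  K1 <- diag(2); K2 <- matrix(1, 2, 2)
  expect_equal(combine_kernels(list(K1, K2), c(1, 0)), K1)
  expect_equal(combine_kernels(list(K2, K2), c(0.5, 0.5)), K2)
  expect_equal(combine_kernels(list(K1, K2), c(0.25, 0.75)),
               matrix(c(1, 0.75, 0.75, 1), 2, 2))
  expect_error(combine_kernels(list(K1, matrix(0, 3, 3)), c(1, 1)),
               class = "mklselect_structural_error")

  # N=2, y=(+1,-1), alpha=(1,1), K=I, eta=1 -> ||w||^2 = 2
  expect_equal(compute_wm_norms(1, c(1, 1), c(1, -1), list(diag(2))), 2)
  expect_equal(compute_wm_norms(c(0, 1), c(1, 1), c(1, -1),
                                list(diag(2), diag(2))), c(0, 2))
  expect_equal(compute_wm_norms(c(1, 1), c(0, 0), c(1, -1),
                                list(diag(2), diag(2))), c(0, 0))
})

test_that("the lp weight update is exactly normalized and matches hand arithmetic", {
  expect_equal(update_eta(rep(4, 5), p = 1), rep(0.2, 5))
  expect_equal(update_eta(c(9, 1), p = 1), c(0.75, 0.25))
  set.seed(4)
  for (p in c(1, 2, 3)) {
    eta <- update_eta(runif(6), p)
    expect_equal(lp_norm <- sum(abs(eta)^p)^(1 / p), 1, tolerance = 1e-10)
    expect_true(all(eta >= 0))
  }
  expect_equal(update_eta(c(0, 5), p = 1), c(0, 1))   # zero norm -> zero weight
  expect_error(update_eta(c(0, 0), p = 1), class = "mklselect_degenerate_error")
})

test_that("training is deterministic, feasible, and degenerates correctly", {
  ds <- make_multisource(two_source_spec(seed = 5, n = 60))
  cfg <- mkl_config(C = 1, p = 1, K = 5, algorithm = 2)
  fit1 <- mkl_train(ds, cfg)
  fit2 <- mkl_train(ds, cfg)
  expect_identical(fit1$eta, fit2$eta)
  expect_identical(fit1$alpha, fit2$alpha)

  # dual feasibility: box constraints and the equality constraint
  expect_true(all(fit1$alpha >= 0 & fit1$alpha <= cfg$C + 1e-9))
  expect_lte(abs(sum(fit1$alpha * ds$labels)), 10 * cfg$tau)
  # weight normalization on the trained model, l1 and l2
  expect_equal(sum(fit1$eta), 1, tolerance = 1e-6)
  fit_l2 <- mkl_train(ds, mkl_config(C = 1, p = 2, K = 5))
  expect_equal(sqrt(sum(fit_l2$eta^2)), 1, tolerance = 1e-6)

  # single source: weight is exactly 1
  one <- subset_sources(ds, "signal")
  expect_equal(unname(mkl_train(one, cfg)$eta), 1)

  # single-class subsets are rejected at construction already
  expect_error(subset_samples(ds, which(ds$labels == 1)),
               class = "mklselect_label_error")
  # and a single-class dataset smuggled past the constructor is caught in train
  smuggled <- ds
  smuggled$labels <- rep(1, n_samples(ds))
  expect_error(mkl_train(smuggled, cfg), class = "mklselect_label_error")
  expect_error(mkl_train(ds, mkl_config(K = 60)),
               class = "mklselect_parameter_error")
})

test_that("l1 training concentrates weight on informative sources across seeds", {
  etas <- t(vapply(1:5, function(sd) {
    ds <- make_multisource(two_source_spec(seed = sd, n = 120))
    std <- standardize(ds)$train
    mkl_train(std, mkl_config(C = 1, p = 1, K = 7))$eta
  }, numeric(2)))
  expect_true(all(etas[, "signal"] > etas[, "static"]))
  # noise suppression: well below the uniform weight 1/P
  expect_lt(mean(etas[, "static"]), 0.25)
})

test_that("prediction uses the kernel expansion with algorithm-specific bandwidths", {
  ds <- make_multisource(two_source_spec(seed = 9, n = 80, delta = 4))
  prep <- prepare_split(ds, seed = 9)
  for (alg in 1:3) {
    fit <- mkl_train(prep$train, mkl_config(C = 1, p = 1, K = 5, algorithm = alg))
    pred <- mkl_predict(fit, prep$test)
    expect_true(all(pred %in% c(-1, 1)))
    rep <- score(prep$test_labels, pred)
    expect_gt(rep$accuracy, 90)   # cleanly separable at delta = 4

    # scoring the support vectors of a clean fit recovers their labels
    sv_ds <- subset_samples(prep$train, fit$sv_indices)
    expect_equal(mkl_predict(fit, sv_ds), prep$train$labels[fit$sv_indices])

    # permuting test order permutes predictions identically
    perm <- rev(seq_len(n_samples(prep$test)))
    expect_equal(mkl_predict(fit, subset_samples(prep$test, perm)), pred[perm])
  }

  # source mismatch is a structural error
  fit <- mkl_train(prep$train, mkl_config(K = 5))
  swapped <- subset_sources(prep$test, rev(prep$test$source_names))
  expect_error(decision_function(fit, swapped),
               class = "mklselect_structural_error")
})

test_that("Algorithms 2 and 3 coincide when every training sample is a support vector", {
  ds <- make_multisource(two_source_spec(seed = 3, n = 40))
  # a tiny C keeps every alpha at the box bound -> all samples are SVs
  fit2 <- mkl_train(ds, mkl_config(C = 1e-3, p = 1, K = 3, algorithm = 2))
  expect_equal(length(fit2$sv_indices), n_samples(ds))
  fit3 <- fit2; fit3$config$algorithm <- 3L
  test <- make_multisource(two_source_spec(seed = 4, n = 20))
  expect_equal(decision_function(fit2, test), decision_function(fit3, test),
               tolerance = 1e-12)
})

test_that("model archives round-trip to identical predictions", {
  ds <- make_multisource(two_source_spec(seed = 6, n = 60))
  prep <- prepare_split(ds, seed = 6)
  fit <- mkl_train(prep$train, mkl_config(K = 5, algorithm = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_mkl_model(fit, path)
  back <- load_mkl_model(path)
  expect_identical(decision_function(back, prep$test),
                   decision_function(fit, prep$test))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_mkl_model(bad), class = "mklselect_config_error")
})
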