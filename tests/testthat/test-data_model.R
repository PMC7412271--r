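test_that("construction validates shapes, labels and finiteness", {
  ds <- multisource_dataset(
    list(A = matrix(1:30, 10, 3), B = matrix(rnorm(50), 10, 5)),
    labels = rep(c(-1, 1), 5)
  )
  expect_equal(n_sources(ds), 2L)
  expect_equal(n_samples(ds), 10L)
  expect_equal(vapply(ds$sources, ncol, integer(1)), c(A = 3L, B = 5L))

  expect_error(
    multisource_dataset(list(A = matrix(0, 10, 3), B = matrix(0, 9, 2)),
                        rep(c(-1, 1), 5)),
    class = "mklselect_structural_error")
  expect_error(
    multisource_dataset(list(A = matrix(0, 4, 2)), c(0, 1, 1, -1)),
    class = "mklselect_label_error")
  expect_error(
    multisource_dataset(list(A = matrix(0, 4, 2)), c(1, 1, 1, 1)),
    class = "mklselect_label_error")
  bad <- matrix(rnorm(8), 4, 2); bad[2, 1] <- NA
  expect_error(multisource_dataset(list(A = bad), c(-1, 1, -1, 1)),
               class = "mklselect_structural_error")
})

test_that("concatenated-table form round-trips to the per-source form", {
  set.seed(11)
  ds <- multisource_dataset(
    list(A = matrix(rnorm(30), 10, 3), B = matrix(rnorm(50), 10, 5)),
    labels = rep(c(-1, 1), 5)
  )
  cc <- as_concatenated(ds)
  expect_equal(dim(cc$X), c(10L, 8L))
  back <- multisource_from_table(cc$X, cc$groups, ds$labels)
  expect_equal(back$source_names, ds$source_names)
  for (nm in ds$source_names)
    expect_equal(unname(back$sources[[nm]]), unname(ds$sources[[nm]]))
  expect_error(multisource_from_table(cc$X, cc$groups[-1], ds$labels),
               class = "mklselect_structural_error")
})

test_that("manifest save -> load round-trips bit-identically", {
  set.seed(5)
  ds <- multisource_dataset(
    list(A = matrix(rnorm(30), 10, 3), B = matrix(rnorm(20), 10, 2)),
    labels = rep(c(-1, 1), 5)
  )
  dir <- withr::local_tempdir()
  manifest <- save_dataset(ds, dir)
  ds2 <- load_dataset(manifest)
  expect_identical(ds2$labels, ds$labels)
  for (nm in ds$source_names)
    expect_identical(unname(ds2$sources[[nm]]), unname(ds$sources[[nm]]))
  # a second round trip through text is exact as well
  dir2 <- withr::local_tempdir()
  ds3 <- load_dataset(save_dataset(ds2, dir2))
  expect_identical(ds3$sources, ds2$sources)
})

test_that("samples-in-columns matrices are transposed on load", {
  dir <- withr::local_tempdir()
  X <- matrix(as.numeric(1:12), 3, 4)   # 3 features x 4 samples on disk
  writeLines(apply(X, 1, paste, collapse = ","), file.path(dir, "A.csv"))
  writeLines(c("1", "-1", "1", "-1"), file.path(dir, "labels.txt"))
  yaml::write_yaml(list(sources = list(list(name = "A", path = "A.csv")),
                        labels = "labels.txt",
                        orientation = "samples_in_columns"),
                   file.path(dir, "manifest.yaml"))
  ds <- load_dataset(file.path(dir, "manifest.yaml"))
  expect_equal(n_samples(ds), 4L)
  expect_equal(unname(ds$sources$A), t(X))
})

test_that("stratified split is exact, deterministic and a partition", {
  spec <- synth_spec(100, list(list(name = "A", n_features = 2,
                                    kind = "noise")), seed = 3)
  ds <- make_multisource(spec)
  out <- split_dataset(ds, split_spec(0.8, TRUE, seed = 9))
  expect_equal(n_samples(out$train), 80L)
  expect_equal(n_samples(out$test), 20L)
  expect_equal(sum(out$train$labels == 1), 40L)
  expect_equal(sum(out$test$labels == 1), 10L)
  expect_setequal(c(out$train_idx, out$test_idx), 1:100)
  expect_length(intersect(out$train_idx, out$test_idx), 0L)
  again <- split_dataset(ds, split_spec(0.8, TRUE, seed = 9))
  expect_identical(again$train_idx, out$train_idx)

  # imbalanced 61/85 case: test size 29-30, per-class counts near 12.2 / 17
  y <- c(rep(-1, 61), rep(1, 85))
  ds2 <- multisource_dataset(list(A = matrix(rnorm(146 * 2), 146, 2)), y)
  out2 <- split_dataset(ds2, split_spec(0.8, TRUE, seed = 4))
  n_test <- n_samples(out2$test)
  expect_true(n_test %in% c(29L, 30L))
  expect_true(abs(sum(out2$test$labels == -1) - 12.2) <= 1)
  expect_true(abs(sum(out2$test$labels == 1) - 17) <= 1)

  tiny <- multisource_dataset(list(A = matrix(rnorm(6), 3, 2)), c(1, 1, -1))
  expect_error(split_dataset(tiny, split_spec(0.8, TRUE, 1)),
               class = "mklselect_split_error")
})

test_that("standardize uses training population statistics and handles degenerate columns", {
  tr <- multisource_dataset(
    list(A = cbind(c(1, 2, 3), c(5, 5, 5))), c(1, -1, 1))
  te <- multisource_dataset(
    list(A = cbind(c(2, 4), c(7, 7))), c(1, -1))
  std <- standardize(tr, list(te))
  expect_equal(std$train$sources$A[, 1],
               c(-1.22474487139159, 0, 1.22474487139159), tolerance = 1e-12)
  expect_equal(std$train$sources$A[, 2], c(0, 0, 0))   # constant -> zeros
  expect_equal(std$others[[1]]$sources$A[, 2], c(0, 0))
  # identical transform applied to test: (2-2)/sd, (4-2)/sd with sd = sqrt(2/3)
  expect_equal(std$others[[1]]$sources$A[, 1], c(0, 2 / sqrt(2 / 3)),
               tolerance = 1e-12)
  expect_identical(std$train$labels, tr$labels)   # labels untouched

  # re-fit on standardized data gives mean 0 and population sd 1
  std2 <- standardize(std$train)
  expect_equal(unname(std2$stats$A$center), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(std2$stats$A$scale[1]), 1, tolerance = 1e-12)
})
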