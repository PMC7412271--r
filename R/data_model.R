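# Multi-source dataset container, manifest-driven I/O, splitting and scaling.

#' Construct a multi-source dataset
#'
#' A multi-source dataset holds P feature matrices (one per information
#' source) over a shared set of N samples, together with a binary label
#' vector in \{-1, +1\}. Sources are aligned by row order: row i of every
#' source matrix describes the same sample.
#'
#' @param sources list of numeric matrices, one per source, each with N rows
#'   (samples) and at least one column (features). All values must be finite.
#' @param labels numeric vector of length N with values in \{-1, +1\}; both
#'   classes must be present.
#' @param source_names character vector of P unique source names; defaults to
#'   `names(sources)` or `S1..SP`.
#' @param sample_ids optional character vector of N sample identifiers.
#' @return An object of class `multisource_dataset` with fields `sources`
#'   (named list of matrices), `labels`, `source_names`, `sample_ids`.
#' @examples
#' ds <- multisource_dataset(
#'   sources = list(A = matrix(rnorm(20), 10), B = matrix(rnorm(30), 10)),
#'   labels = rep(c(-1, 1), 5)
#' )
#' ds
#' @export
multisource_dataset <- function(sources, labels, source_names = NULL,
                                sample_ids = NULL) {
  if (!is.list(sources) || length(sources) < 1L)
    mkl_stop("structural", "`sources` must be a non-empty list of matrices")
  if (is.null(source_names)) {
    source_names <- names(sources)
    if (is.null(source_names) || any(!nzchar(source_names)))
      source_names <- paste0("S", seq_along(sources))
  }
  if (length(source_names) != length(sources) || anyDuplicated(source_names))
    mkl_stop("structural", "source names must be unique and one per source")
  sources <- lapply(sources, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  names(sources) <- source_names
  n <- nrow(sources[[1L]])
  for (m in seq_along(sources)) {
    X <- sources[[m]]
    if (nrow(X) != n)
      mkl_stop("structural", sprintf(
        "source '%s' has %d rows but source '%s' has %d: sample counts must match",
        source_names[m], nrow(X), source_names[1L], n))
    if (ncol(X) < 1L)
      mkl_stop("structural", sprintf("source '%s' has no feature columns",
                                     source_names[m]))
    if (!all(is.finite(X)))
      mkl_stop("structural", sprintf("source '%s' contains non-finite values",
                                     source_names[m]))
  }
  labels <- as.numeric(labels)
  if (length(labels) != n)
    mkl_stop("label", sprintf("labels have length %d but sources have %d samples",
                              length(labels), n))
  if (!all(labels %in% c(-1, 1)))
    mkl_stop("label", "labels must take values in {-1, +1}")
  if (length(unique(labels)) < 2L)
    mkl_stop("label", "both classes must be present")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  if (length(sample_ids) != n)
    mkl_stop("structural", "sample_ids must have one entry per sample")
  structure(
    list(sources = sources, labels = labels,
         source_names = source_names, sample_ids = as.character(sample_ids)),
    class = "multisource_dataset"
  )
}

#' @export
print.multisource_dataset <- function(x, ...) {
  d <- vapply(x$sources, ncol, integer(1))
  cat(sprintf("multisource_dataset: %d samples, %d source(s)\n",
              n_samples(x), n_sources(x)))
  cat(sprintf("  labels: %d of class +1, %d of class -1\n",
              sum(x$labels == 1), sum(x$labels == -1)))
  cat("  sources (features): ",
      paste(sprintf("%s (%d)", x$source_names, d), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of samples / sources in a multi-source dataset
#' @param ds a `multisource_dataset`.
#' @return An integer count.
#' @export
n_samples <- function(ds) nrow(ds$sources[[1L]])

#' @rdname n_samples
#' @export
n_sources <- function(ds) length(ds$sources)

#' Subset samples or sources of a multi-source dataset
#'
#' @param ds a `multisource_dataset`.
#' @param idx integer vector of sample indices (`subset_samples`).
#' @param which character vector of source names or integer indices, in the
#'   desired order (`subset_sources`).
#' @return A new `multisource_dataset`.
#' @export
subset_samples <- function(ds, idx) {
  multisource_dataset(
    lapply(ds$sources, function(X) X[idx, , drop = FALSE]),
    ds$labels[idx],
    source_names = ds$source_names,
    sample_ids = ds$sample_ids[idx]
  )
}

#' @rdname subset_samples
#' @export
subset_sources <- function(ds, which) {
  if (is.character(which)) {
    missing <- setdiff(which, ds$source_names)
    if (length(missing))
      mkl_stop("structural", paste("unknown source(s):",
                                   paste(missing, collapse = ", ")))
  }
  multisource_dataset(
    ds$sources[which], ds$labels,
    source_names = if (is.character(which)) which else ds$source_names[which],
    sample_ids = ds$sample_ids
  )
}

#' Concatenated-table view of a multi-source dataset
#'
#' `as_concatenated()` binds all source blocks into one feature table plus a
#' group map (the factor assigning each column to its source);
#' `multisource_from_table()` is the inverse, rebuilding the per-source form
#' from a concatenated table and a group map.
#'
#' @param ds a `multisource_dataset`.
#' @return For `as_concatenated()`, a list with `X` (N x sum(Dm) matrix) and
#'   `groups` (factor of length ncol(X), levels in source order).
#' @export
as_concatenated <- function(ds) {
  X <- do.call(cbind, ds$sources)
  groups <- factor(
    rep(ds$source_names, vapply(ds$sources, ncol, integer(1))),
    levels = ds$source_names
  )
  colnames(X) <- paste0(as.character(groups), ".",
                        unlist(lapply(ds$sources, function(x) seq_len(ncol(x)))))
  list(X = X, groups = groups)
}

#' @rdname as_concatenated
#' @param X numeric matrix of concatenated features (samples in rows).
#' @param groups factor or character vector of length `ncol(X)` assigning each
#'   feature column to a source; every named source must receive at least one
#'   column.
#' @param labels,sample_ids as in [multisource_dataset()].
#' @export
multisource_from_table <- function(X, groups, labels, sample_ids = NULL) {
  X <- as.matrix(X)
  if (length(groups) != ncol(X))
    mkl_stop("structural", "group map must assign every feature column to a source")
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (any(table(groups) == 0L))
    mkl_stop("structural", "every named source must receive at least one column")
  sources <- lapply(levels(groups), function(g) X[, groups == g, drop = FALSE])
  multisource_dataset(sources, labels, source_names = levels(groups),
                      sample_ids = sample_ids)
}

# ---------------------------------------------------------------------------
# Manifest-driven I/O
#
# Manifest (YAML): either per-source matrices
#   sources: [{name: A, path: A.csv}, {name: B, path: B.csv}]
#   labels: labels.txt
#   orientation: samples_in_rows | samples_in_columns   (default samples_in_rows)
#   delimiter: ","                                       (default)
#   header: false                                        (default)
# or a concatenated table plus group map (one source name per feature column):
#   table: X.csv
#   group_map: groups.txt
#   labels: labels.txt
# Paths are resolved relative to the manifest's directory.
# ---------------------------------------------------------------------------

read_delim_matrix <- function(path, delimiter, header) {
  df <- utils::read.table(path, sep = delimiter, header = header,
                          colClasses = "numeric", comment.char = "")
  as.matrix(df)
}

#' Load a multi-source dataset described by a manifest file
#'
#' The manifest is a small YAML file listing either one delimited-text matrix
#' per source plus a label file, or a single concatenated feature table plus a
#' group-map file (one source name per feature column). Matrices may be
#' stored samples-in-rows (default) or samples-in-columns (set
#' `orientation: samples_in_columns`); they are converted to samples-in-rows
#' on load.
#'
#' @param manifest_path path to the manifest YAML file.
#' @return A validated [multisource_dataset()]; source order follows the
#'   manifest.
#' @seealso [save_dataset()] for the writer producing this layout.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    mkl_stop("config", paste("manifest not found:", manifest_path))
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  delimiter <- man$delimiter %||% ","
  header <- isTRUE(man$header)
  orientation <- man$orientation %||% "samples_in_rows"
  if (!orientation %in% c("samples_in_rows", "samples_in_columns"))
    mkl_stop("config", "orientation must be samples_in_rows or samples_in_columns")
  if (is.null(man$labels)) mkl_stop("config", "manifest must name a label file")
  labels <- scan(resolve(man$labels), what = numeric(), quiet = TRUE)

  if (!is.null(man$table)) {
    X <- read_delim_matrix(resolve(man$table), delimiter, header)
    if (orientation == "samples_in_columns") X <- t(X)
    if (is.null(man$group_map))
      mkl_stop("config", "concatenated-table manifests need a group_map file")
    groups <- scan(resolve(man$group_map), what = character(), quiet = TRUE)
    return(multisource_from_table(X, groups, labels))
  }
  if (is.null(man$sources) || !length(man$sources))
    mkl_stop("config", "manifest lists no sources")
  mats <- lapply(man$sources, function(s) {
    X <- read_delim_matrix(resolve(s$path), delimiter, header)
    if (orientation == "samples_in_columns") X <- t(X)
    X
  })
  nm <- vapply(man$sources, function(s) as.character(s$name), character(1))
  multisource_dataset(mats, labels, source_names = nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multi-source dataset as delimited text plus a manifest
#'
#' Writes one CSV per source (samples in rows, full double precision so that
#' load -> save -> load round-trips exactly), a label file (one label per
#' line), and a `manifest.yaml` readable by [load_dataset()].
#'
#' @param ds a `multisource_dataset`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(X) apply(X, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  paths <- character(0)
  for (nm in ds$source_names) {
    p <- paste0(nm, ".csv")
    writeLines(fmt(ds$sources[[nm]]), file.path(dir, p))
    paths <- c(paths, p)
  }
  writeLines(formatC(ds$labels, format = "d"), file.path(dir, "labels.txt"))
  man <- list(
    sources = Map(function(n, p) list(name = n, path = p), ds$source_names, paths),
    labels = "labels.txt",
    orientation = "samples_in_rows",
    delimiter = ",",
    header = FALSE
  )
  names(man$sources) <- NULL
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, manifest)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# Splitting and scaling
# ---------------------------------------------------------------------------

#' Train/test split specification
#'
#' @param train_fraction proportion of samples used for training, in (0, 1);
#'   default 0.8 (a held-out 20% test set).
#' @param stratified draw the split per class so class proportions are
#'   preserved within one sample? Default `TRUE`.
#' @param seed integer seed making the split deterministic.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (!is_scalar_num(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    mkl_stop("parameter", "train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a multi-source dataset into train and test parts
#'
#' @param ds a `multisource_dataset`.
#' @param spec a [split_spec()].
#' @return A list with elements `train` and `test` (both
#'   `multisource_dataset`) and the integer index vectors `train_idx`,
#'   `test_idx`. The two index sets partition `1:N`.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- n_samples(ds)
  train_idx <- with_seed(spec$seed, {
    if (spec$stratified) {
      idx <- integer(0)
      for (cl in c(-1, 1)) {
        members <- which(ds$labels == cl)
        if (length(members) < 2L)
          mkl_stop("split", sprintf(
            "class %+d has fewer than 2 samples; cannot stratify", cl))
        k <- floor(spec$train_fraction * length(members) + 0.5)
        k <- min(max(k, 1L), length(members) - 1L)
        idx <- c(idx, sample(members)[seq_len(k)])
      }
      sort(idx)
    } else {
      k <- floor(spec$train_fraction * n + 0.5)
      k <- min(max(k, 1L), n - 1L)
      sort(sample(n)[seq_len(k)])
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_samples(ds, train_idx),
       test = subset_samples(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Standardize features using training statistics only
#'
#' Each feature column is z-scored with the training mean and population
#' standard deviation; the identical transform is applied to any further
#' datasets (test sets, validation folds), so no information leaks from them.
#' Zero-variance columns map to all-zeros. Labels are untouched. Gaussian
#' kernels are scale-sensitive, so this is applied before any kernel
#' computation in the bundled pipelines.
#'
#' @param train a `multisource_dataset` providing the statistics.
#' @param others list of further `multisource_dataset`s to transform with the
#'   training statistics.
#' @return A list with `train`, `others` (same shapes as the inputs) and
#'   `stats` (per-source centers and scales).
#' @export
standardize <- function(train, others = list()) {
  if (inherits(others, "multisource_dataset")) others <- list(others)
  stats <- lapply(train$sources, function(X) {
    mu <- colMeans(X)
    sdp <- sqrt(colMeans(sweep(X, 2L, mu)^2))   # population sd
    list(center = mu, scale = sdp)
  })
  apply_one <- function(ds) {
    z <- lapply(ds$source_names, function(nm) {
      st <- stats[[nm]]
      X <- sweep(ds$sources[[nm]], 2L, st$center)
      sc <- ifelse(st$scale > 0, st$scale, 1)
      X <- sweep(X, 2L, sc, "/")
      X[, st$scale == 0] <- 0
      X
    })
    names(z) <- ds$source_names
    multisource_dataset(z, ds$labels, source_names = ds$source_names,
                        sample_ids = ds$sample_ids)
  }
  list(train = apply_one(train), others = lapply(others, apply_one),
       stats = stats)
}
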