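# canonical column order for process datasets (matches the reference
# calibration's input order, target last)
process_columns <- function() c("pH", "DMP_in", "DO", "ORP", "MLSS", "DMP_eff")

#' Construct / validate a process dataset
#'
#' A process dataset holds one row per sampling event of the A/A/O train:
#' pH (unitless), influent DMP (ug L^-1), aerobic-zone dissolved oxygen
#' (mg L^-1), ORP (mV), MLSS (mg L^-1), and the target, effluent DMP
#' (ug L^-1). Columns are matched case-insensitively and reordered to the
#' canonical order. All cells must be numeric and non-missing;
#' concentrations must be non-negative (ORP may be negative).
#'
#' @param df Data frame with the six columns.
#' @param provenance `"measured"` or `"synthetic"`.
#' @return A data frame of class `process_dataset` with a `provenance`
#'   attribute.
#' @export
process_dataset <- function(df, provenance = c("measured", "synthetic")) {
  provenance <- match.arg(provenance)
  want <- process_columns()
  idx <- match(tolower(want), tolower(names(df)))
  if (anyNA(idx)) {
    fwnn_stop(sprintf("missing column(s): %s",
                      paste(want[is.na(idx)], collapse = ", ")),
              "fwnndmp_schema_error")
  }
  df <- df[, idx]
  names(df) <- want
  for (col in want) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      fwnn_stop(sprintf("column %s is not numeric", col),
                "fwnndmp_schema_error")
    }
    if (anyNA(v)) {
      fwnn_stop(sprintf("missing value in column %s (row %d)",
                        col, which(is.na(v))[1]),
                "fwnndmp_schema_error")
    }
  }
  for (col in c("pH", "DMP_in", "DO", "MLSS", "DMP_eff")) {
    if (any(df[[col]] < 0)) {
      fwnn_stop(sprintf("negative value in column %s (row %d)",
                        col, which(df[[col]] < 0)[1]),
                "fwnndmp_schema_error")
    }
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("process_dataset", "data.frame"))
}

#' Read a process dataset from CSV
#'
#' Expects a header with the six canonical columns (case-insensitive, any
#' order): `pH, DMP_in, DO, ORP, MLSS, DMP_eff`.
#'
#' @param path CSV file path.
#' @param provenance Provenance tag to attach.
#' @return A `process_dataset`.
#' @export
read_process_dataset <- function(path, provenance = "measured") {
  if (!file.exists(path)) {
    fwnn_stop(sprintf("dataset file not found: %s", path), "fwnndmp_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  process_dataset(df, provenance)
}

#' Write a process dataset to CSV
#'
#' @param dataset A `process_dataset`.
#' @param path Output path.
#' @export
write_process_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Fit a column scaling specification
#'
#' Learns per-column scaling from a dataset. `minmax_sym` (default) maps
#' the observed `[min, max]` to `[-1, 1]` — consistent with the near-origin
#' centers and translations of the reference network calibration;
#' `minmax_unit` maps to `[0, 1]`; `zscore` centers to mean 0, sd 1. Fit
#' the specification on the training split only and apply it to both splits
#' to avoid leakage.
#'
#' @param dataset A `process_dataset` or plain data frame of numeric
#'   columns.
#' @param method Scaling method.
#' @return A list of class `scaling_spec`.
#' @export
fit_scaling <- function(dataset, method = c("minmax_sym", "minmax_unit",
                                            "zscore")) {
  method <- match.arg(method)
  cols <- lapply(dataset, function(v) {
    if (method == "zscore") {
      s <- stats::sd(v)
      if (s == 0) {
        fwnn_stop("constant column: sd = 0", "fwnndmp_degenerate_column")
      }
      c(center = mean(v), scale = s)
    } else {
      lo <- min(v); hi <- max(v)
      if (hi <= lo) {
        fwnn_stop("constant column: max must exceed min",
                  "fwnndmp_degenerate_column")
      }
      c(min = lo, max = hi)
    }
  })
  structure(list(method = method, columns = cols), class = "scaling_spec")
}

scale_column <- function(v, spec, column) {
  p <- spec$columns[[column]]
  if (is.null(p)) {
    fwnn_stop(sprintf("scaling spec has no column '%s'", column),
              "fwnndmp_schema_error")
  }
  switch(spec$method,
    minmax_sym = 2 * (v - p["min"]) / (p["max"] - p["min"]) - 1,
    minmax_unit = (v - p["min"]) / (p["max"] - p["min"]),
    zscore = (v - p["center"]) / p["scale"]
  ) |> unname()
}

invert_column <- function(v, spec, column) {
  p <- spec$columns[[column]]
  if (is.null(p)) {
    fwnn_stop(sprintf("scaling spec has no column '%s'", column),
              "fwnndmp_schema_error")
  }
  switch(spec$method,
    minmax_sym = (v + 1) / 2 * (p["max"] - p["min"]) + p["min"],
    minmax_unit = v * (p["max"] - p["min"]) + p["min"],
    zscore = v * p["scale"] + p["center"]
  ) |> unname()
}

#' Apply / invert a scaling specification
#'
#' `apply_scaling` transforms every column named in the spec;
#' `invert_scaling` is its exact inverse (to floating precision).
#'
#' @param dataset Data frame whose columns appear in the spec.
#' @param spec A [fit_scaling()] result.
#' @return Data frame of the same shape in scaled (or original) units.
#' @export
apply_scaling <- function(dataset, spec) {
  out <- as.data.frame(dataset)
  for (col in intersect(names(out), names(spec$columns))) {
    out[[col]] <- scale_column(out[[col]], spec, col)
  }
  out
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(dataset, spec) {
  out <- as.data.frame(dataset)
  for (col in intersect(names(out), names(spec$columns))) {
    out[[col]] <- invert_column(out[[col]], spec, col)
  }
  out
}

#' Read / write a scaling specification as JSON
#'
#' @param spec A `scaling_spec`; @param path file path.
#' @export
write_scaling_spec <- function(spec, path) {
  jsonlite::write_json(
    list(method = spec$method,
         columns = lapply(spec$columns, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling_spec
#' @export
read_scaling_spec <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cols <- lapply(raw$columns, function(p) unlist(p))
  structure(list(method = raw$method, columns = cols), class = "scaling_spec")
}

#' Seeded train/test partition
#'
#' Random partition without replacement; default 35 training rows (the
#' study's 35/15 split of its 50 samples). The two splits are disjoint and
#' exhaustive, and reproducible under a fixed seed.
#'
#' @param dataset A `process_dataset` or data frame.
#' @param n_train Training set size (< number of rows).
#' @param seed RNG seed.
#' @return List with `train`, `test`, `train_idx`, `seed`.
#' @export
split_dataset <- function(dataset, n_train = 35, seed = 1) {
  n <- nrow(dataset)
  if (n_train >= n) {
    fwnn_stop("n_train must be smaller than the number of rows",
              "fwnndmp_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(n, n_train))
  train <- dataset[idx, , drop = FALSE]
  test <- dataset[-idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, train_idx = idx, seed = seed)
}
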