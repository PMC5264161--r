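#' Prediction performance metrics
#'
#' Computes the four statistics used throughout the evaluation harness:
#' \itemize{
#'   \item MSE: \eqn{\mathrm{mean}((o - p)^2)}
#'   \item RMSE: \eqn{\sqrt{\mathrm{MSE}}}
#'   \item MAPE (percent): \eqn{100 \cdot \mathrm{mean}(|o - p| / |o|)}
#'   \item \eqn{R^2}: \eqn{1 - \sum(o-p)^2 / \sum(o - \bar o)^2}
#' }
#' MAPE is reported as `NA` (with a flag) when any observed value is zero;
#' \eqn{R^2} is `NA` when the observations have zero variance.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 1).
#' @return A list of class `model_metrics` with `r_squared`, `mape`,
#'   `rmse`, `mse`, `n` and logical flags `mape_undefined`,
#'   `r_squared_undefined`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    fwnn_stop("observed and predicted must have equal length",
              "fwnndmp_schema_error")
  }
  if (length(observed) < 1) {
    fwnn_stop("need at least one observation", "fwnndmp_invalid_input")
  }
  err <- observed - predicted
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  mape_undef <- any(observed == 0)
  mape <- if (mape_undef) NA_real_ else 100 * mean(abs(err) / abs(observed))
  sstot <- sum((observed - mean(observed))^2)
  r2_undef <- sstot == 0
  r2 <- if (r2_undef) NA_real_ else 1 - sum(err^2) / sstot
  structure(
    list(r_squared = r2, mape = mape, rmse = rmse, mse = mse,
         n = length(observed),
         mape_undefined = mape_undef, r_squared_undefined = r2_undef),
    class = "model_metrics"
  )
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("R2 %.4f | MAPE %.4f%% | RMSE %.4g | MSE %.4g | n %d\n",
              x$r_squared, x$mape, x$rmse, x$mse, x$n))
  invisible(x)
}

#' Three-model comparison on one held-out split
#'
#' Evaluates the trained FWNN, the GA-NN baseline and the kinetic chain on
#' the identical test split and lays the result out as a metric-by-model
#' table (rows R2, MAPE, RMSE, MSE; columns FWNN, GA-NN, Kinetic).
#'
#' @param observed Observed effluent DMP on the test split.
#' @param fwnn_pred,nn_pred,kinetic_pred Predictions from the three models
#'   on the same split, in the same units as `observed`.
#' @return Data frame of class `model_comparison` (4 rows x 3 columns, plus
#'   a `metric` column).
#' @export
compare_models <- function(observed, fwnn_pred, nn_pred, kinetic_pred) {
  lens <- c(length(fwnn_pred), length(nn_pred), length(kinetic_pred))
  if (any(lens != length(observed))) {
    fwnn_stop("all models must be evaluated on the identical test split",
              "fwnndmp_split_mismatch")
  }
  ms <- lapply(list(fwnn_pred, nn_pred, kinetic_pred),
               function(p) compute_metrics(observed, p))
  out <- data.frame(
    metric = c("R2", "MAPE", "RMSE", "MSE"),
    FWNN = unlist(ms[[1]][c("r_squared", "mape", "rmse", "mse")]),
    GA_NN = unlist(ms[[2]][c("r_squared", "mape", "rmse", "mse")]),
    Kinetic = unlist(ms[[3]][c("r_squared", "mape", "rmse", "mse")]),
    row.names = NULL
  )
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Predicting performance by model\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' End-to-end comparison harness on a process dataset
#'
#' The full workflow behind the comparison table: split the dataset
#' (default 35 training / remaining test), fit the scaling on the training
#' split only, train the FWNN by hybrid GA + gradient descent and the GA-NN
#' baseline by the same schedule, predict the test split with both (inverse
#' scaled back to concentration units), run the simplified pure-Monod
#' kinetic chain on the same test rows, and tabulate metrics.
#'
#' @param dataset A `process_dataset` (see [process_dataset()]).
#' @param n_train Training split size.
#' @param n_rules FWNN rule count.
#' @param hidden_units Baseline hidden layer width.
#' @param ga,gd Training configurations shared by both learned models.
#' @param kinetic_zones Zone chain for the kinetic comparator (default
#'   [aao_zone_chain()]); it is run in pure-Monod mode, the simplified rate
#'   law the calibration constants parameterize.
#' @param seed Seed controlling the split and both training runs.
#' @param scaled_metrics If `TRUE`, metrics are computed in scaled target
#'   units instead of concentration units.
#' @return List with `table` (a `model_comparison`), `fwnn_report`,
#'   `nn_report`, `split`, `scaling`, `seed`.
#' @export
run_comparison <- function(dataset, n_train = 35, n_rules = 8,
                           hidden_units = 5, ga = ga_config(),
                           gd = gd_config(), kinetic_zones = aao_zone_chain(),
                           seed = 1, scaled_metrics = FALSE) {
  split <- split_dataset(dataset, n_train = n_train, seed = seed)
  spec <- fit_scaling(split$train)
  tr <- apply_scaling(split$train, spec)
  te <- apply_scaling(split$test, spec)
  xcols <- setdiff(names(tr), "DMP_eff")

  fwnn_report <- fwnn_hybrid_train(
    as.matrix(tr[, xcols]), tr$DMP_eff,
    as.matrix(te[, xcols]), te$DMP_eff,
    n_rules = n_rules, ga = ga, gd = gd, seed = seed
  )
  nn_report <- baseline_nn_train(
    as.matrix(tr[, xcols]), tr$DMP_eff,
    as.matrix(te[, xcols]), te$DMP_eff,
    hidden_units = hidden_units, ga = ga, gd = gd, seed = seed + 1
  )

  fwnn_scaled <- fwnn_predict(fwnn_report$final_params, as.matrix(te[, xcols]))
  nn_scaled <- mlp_predict(nn_report$final_params, as.matrix(te[, xcols]))
  kin_pred <- vapply(seq_len(nrow(split$test)), function(i) {
    predict_effluent(split$test$DMP_in[i], kinetic_zones,
                     X_H = split$test$MLSS[i], switching = FALSE)
  }, numeric(1))

  if (scaled_metrics) {
    observed <- te$DMP_eff
    fwnn_pred <- fwnn_scaled
    nn_pred <- nn_scaled
    kin_scaled <- scale_column(kin_pred, spec, "DMP_eff")
    tab <- compare_models(observed, fwnn_pred, nn_pred, kin_scaled)
  } else {
    observed <- split$test$DMP_eff
    fwnn_pred <- invert_column(fwnn_scaled, spec, "DMP_eff")
    nn_pred <- invert_column(nn_scaled, spec, "DMP_eff")
    tab <- compare_models(observed, fwnn_pred, nn_pred, kin_pred)
  }

  list(table = tab, fwnn_report = fwnn_report, nn_report = nn_report,
       split = split, scaling = spec, seed = seed)
}
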