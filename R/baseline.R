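# GA-NN baseline: single-hidden-layer perceptron (tanh hidden, linear
# output) trained by the same GA -> gradient-descent schedule as the FWNN.
# Used only by the three-model comparison harness.

mlp_n_genes <- function(n_inputs, hidden_units) {
  if (hidden_units == 0) n_inputs + 1 else hidden_units * (n_inputs + 2) + 1
}

mlp_decode <- function(chromosome, n_inputs, hidden_units) {
  if (length(chromosome) != mlp_n_genes(n_inputs, hidden_units)) {
    fwnn_stop("baseline chromosome has wrong length", "fwnndmp_schema_error")
  }
  if (hidden_units == 0) {
    list(beta = chromosome[seq_len(n_inputs)],
         intercept = chromosome[n_inputs + 1],
         hidden_units = 0, n_inputs = n_inputs)
  } else {
    h <- hidden_units
    k <- h * n_inputs
    list(W1 = matrix(chromosome[1:k], h, n_inputs, byrow = TRUE),
         b1 = chromosome[(k + 1):(k + h)],
         w2 = chromosome[(k + h + 1):(k + 2 * h)],
         b2 = chromosome[k + 2 * h + 1],
         hidden_units = h, n_inputs = n_inputs)
  }
}

mlp_encode <- function(net) {
  if (net$hidden_units == 0) {
    c(net$beta, net$intercept)
  } else {
    c(as.vector(t(net$W1)), net$b1, net$w2, net$b2)
  }
}

#' Baseline perceptron forward pass
#'
#' Predicts with the comparison network: `hidden_units = 0` is plain linear
#' regression; otherwise a single tanh hidden layer with linear output.
#'
#' @param net Decoded baseline network (internal list form).
#' @param X Scaled input matrix.
#' @return Numeric vector of predictions.
#' @export
mlp_predict <- function(net, X) {
  X <- as.matrix(X)
  if (net$hidden_units == 0) {
    as.numeric(X %*% net$beta + net$intercept)
  } else {
    H <- tanh(sweep(X %*% t(net$W1), 2, net$b1, "+"))  # n x h
    as.numeric(H %*% net$w2 + net$b2)
  }
}

# analytic batch gradient of mean squared error for the perceptron
mlp_gradients <- function(net, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (net$hidden_units == 0) {
    pred <- mlp_predict(net, X)
    e <- 2 * (pred - y) / n
    list(grad = c(as.numeric(t(X) %*% e), sum(e)),
         mse = mean((pred - y)^2))
  } else {
    A <- sweep(X %*% t(net$W1), 2, net$b1, "+")
    H <- tanh(A)
    pred <- as.numeric(H %*% net$w2 + net$b2)
    e <- 2 * (pred - y) / n
    g_w2 <- as.numeric(t(H) %*% e)
    g_b2 <- sum(e)
    D <- (e %o% net$w2) * (1 - H^2)   # n x h
    g_W1 <- t(D) %*% X                # h x p
    g_b1 <- colSums(D)
    list(grad = c(as.vector(t(g_W1)), g_b1, g_w2, g_b2),
         mse = mean((pred - y)^2))
  }
}

#' Train the GA-NN comparison baseline
#'
#' Single-hidden-layer perceptron trained with the identical schedule used
#' for the fuzzy wavelet network: real-coded GA (fitness `1/(1+MSE)`)
#' followed by full-batch gradient descent, with best-so-far tracking.
#'
#' @param x_train,y_train Scaled training split.
#' @param x_test,y_test Optional scaled test split.
#' @param hidden_units Hidden layer width; 0 reduces the model to linear
#'   regression.
#' @param ga A [ga_config()]; @param gd a [gd_config()].
#' @param seed RNG seed for the whole run.
#' @return A `training_report` whose `final_params` is the fitted network
#'   (internal list form usable with [mlp_predict()]).
#' @export
baseline_nn_train <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                              hidden_units = 5, ga = ga_config(),
                              gd = gd_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_train <- as.matrix(x_train)
  p <- ncol(x_train)
  ngene <- mlp_n_genes(p, hidden_units)
  fitness_fn <- function(ch) {
    pred <- mlp_predict(mlp_decode(ch, p, hidden_units), x_train)
    if (any(!is.finite(pred))) return(0)
    1 / (1 + mean((pred - y_train)^2))
  }
  ga_res <- ga_optimize(
    fitness_fn = fitness_fn,
    init_fn = function() stats::runif(ngene, -1, 1),
    config = ga, mutation_sd = 0.2
  )
  net <- mlp_decode(ga_res$best, p, hidden_units)
  # gradient descent with best-so-far tracking, mirroring fwnn_gd_train
  cur <- ga_res$best
  g0 <- mlp_gradients(net, x_train, y_train)
  best <- cur; best_mse <- g0$mse
  trace <- numeric(0)
  for (ep in seq_len(gd$max_epochs)) {
    g <- mlp_gradients(mlp_decode(cur, p, hidden_units), x_train, y_train)
    cur <- cur - gd$learning_rate * g$grad
    mse <- mlp_gradients(mlp_decode(cur, p, hidden_units),
                         x_train, y_train)$mse
    if (!is.finite(mse)) {
      fwnn_stop(sprintf("baseline training diverged at epoch %d", ep),
                "fwnndmp_divergence")
    }
    trace <- c(trace, mse)
    if (mse < best_mse) { best <- cur; best_mse <- mse }
    if (mse <= gd$target_error) break
  }
  final <- mlp_decode(best, p, hidden_units)
  train_pred <- mlp_predict(final, x_train)
  train_metrics <- compute_metrics(y_train, train_pred)
  test_metrics <- NULL
  if (!is.null(x_test)) {
    test_metrics <- compute_metrics(y_test, mlp_predict(final, as.matrix(x_test)))
  }
  structure(
    list(ga_best_fitness_per_generation = ga_res$trace,
         gd_train_mse_per_epoch = c(g0$mse, trace),
         final_params = final,
         train_metrics = train_metrics, test_metrics = test_metrics,
         seed = seed, model = "ga_nn"),
    class = "training_report"
  )
}
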