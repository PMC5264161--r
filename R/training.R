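#' Genetic algorithm configuration
#'
#' Defaults follow the study conditions for the full model: population 100,
#' crossover rate 0.3, per-gene mutation rate 0.09, 200 generations. The GA
#' is real-coded with tournament selection (size 2), arithmetic (blend)
#' crossover, per-gene Gaussian mutation (sd = 10% of the initialization
#' range) and elitism.
#'
#' @param population_size Number of chromosomes (>= 2).
#' @param crossover_rate Probability a selected pair is blended.
#' @param mutation_rate Per-gene mutation probability.
#' @param max_generations Number of generations.
#' @param elitism_count Number of best individuals copied unchanged.
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @param init_ranges Named list of `(low, high)` initialization bounds per
#'   parameter group (`centers`, `spreads`, `dilations`, `translations`,
#'   `weights`). Spreads and dilations are drawn in magnitude from their
#'   range with random sign.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, crossover_rate = 0.3,
                      mutation_rate = 0.09, max_generations = 200,
                      elitism_count = 2, seed = NULL,
                      init_ranges = list(
                        centers = c(-2, 2), spreads = c(0.1, 3),
                        dilations = c(0.1, 3), translations = c(-2, 2),
                        weights = c(-3, 3)
                      )) {
  if (population_size < 2) {
    fwnn_stop("population_size must be at least 2", "fwnndmp_config_error")
  }
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    fwnn_stop("rates must lie in [0, 1]", "fwnndmp_config_error")
  }
  if (elitism_count < 1) {
    fwnn_stop("elitism_count must be at least 1", "fwnndmp_config_error")
  }
  structure(
    list(population_size = population_size, crossover_rate = crossover_rate,
         mutation_rate = mutation_rate, max_generations = max_generations,
         elitism_count = elitism_count, seed = seed,
         init_ranges = init_ranges),
    class = "ga_config"
  )
}

#' Gradient descent configuration
#'
#' @param learning_rate Step size for full-batch gradient descent (> 0).
#' @param max_epochs Maximum number of epochs.
#' @param target_error Stop once the training MSE (scaled units) falls to or
#'   below this threshold.
#' @param gradient_mode `"analytic"` (closed-form partials) or `"numeric"`
#'   (central finite differences, mainly for cross-checking).
#' @return A list of class `gd_config`.
#' @export
gd_config <- function(learning_rate = 0.01, max_epochs = 500,
                      target_error = 1e-4,
                      gradient_mode = c("analytic", "numeric")) {
  gradient_mode <- match.arg(gradient_mode)
  if (learning_rate <= 0) {
    fwnn_stop("learning_rate must be positive", "fwnndmp_config_error")
  }
  if (target_error < 0) {
    fwnn_stop("target_error must be non-negative", "fwnndmp_config_error")
  }
  structure(
    list(learning_rate = learning_rate, max_epochs = max_epochs,
         target_error = target_error, gradient_mode = gradient_mode),
    class = "gd_config"
  )
}

#' Encode FWNN parameters as a flat chromosome
#'
#' Fixed deterministic layout: centers row-major, then spreads, dilations,
#' translations, weights. `fwnn_decode(fwnn_encode(p))` reproduces `p`
#' exactly.
#'
#' @param params An `fwnn_params` object.
#' @return Numeric vector of length `n_rules * (4 * n_inputs) + n_rules`.
#' @export
fwnn_encode <- function(params) {
  c(as.vector(t(params$centers)), as.vector(t(params$spreads)),
    as.vector(t(params$dilations)), as.vector(t(params$translations)),
    params$weights)
}

#' Decode a flat chromosome into FWNN parameters
#'
#' Inverse of [fwnn_encode()]. Spread and dilation genes with magnitude
#' below `1e-6` are clamped to `+/- 1e-6` (they enter the network as
#' divisors).
#'
#' @param chromosome Numeric vector produced by [fwnn_encode()] or by the GA.
#' @param n_inputs,n_rules Network dimensions.
#' @param input_names,aggregation,wavelet Passed to [fwnn_params()].
#' @return An `fwnn_params` object.
#' @export
fwnn_decode <- function(chromosome, n_inputs, n_rules, input_names = NULL,
                        aggregation = "normalized", wavelet = "mexhat") {
  expected <- n_rules * 4 * n_inputs + n_rules
  if (length(chromosome) != expected) {
    fwnn_stop(sprintf("chromosome has length %d, expected %d",
                      length(chromosome), expected),
              "fwnndmp_schema_error")
  }
  k <- n_rules * n_inputs
  take <- function(i) {
    matrix(chromosome[((i - 1) * k + 1):(i * k)], nrow = n_rules,
           ncol = n_inputs, byrow = TRUE)
  }
  clamp_div <- function(m) {
    small <- abs(m) < 1e-6
    m[small] <- ifelse(m[small] < 0, -1e-6, 1e-6)
    m
  }
  fwnn_params(
    centers = take(1), spreads = clamp_div(take(2)),
    dilations = clamp_div(take(3)), translations = take(4),
    weights = chromosome[(4 * k + 1):(4 * k + n_rules)],
    input_names = input_names, aggregation = aggregation, wavelet = wavelet
  )
}

#' GA fitness of a chromosome on a scaled dataset
#'
#' Fitness is `1 / (1 + MSE)` of the decoded network's predictions, bounded
#' in `(0, 1]` and monotone decreasing in MSE. Degenerate activation (no
#' rule fires for some sample) yields fitness 0 rather than an error, so the
#' GA search remains robust.
#'
#' @param chromosome Flat parameter vector.
#' @param x Scaled input matrix (`n x n_inputs`).
#' @param y Scaled target vector.
#' @param n_rules Number of rules implied by the chromosome.
#' @param aggregation,wavelet Forward-pass settings.
#' @return Fitness in `[0, 1]`.
#' @export
fwnn_fitness <- function(chromosome, x, y, n_rules,
                         aggregation = "normalized", wavelet = "mexhat") {
  p <- fwnn_decode(chromosome, ncol(x), n_rules,
                   aggregation = aggregation, wavelet = wavelet)
  pred <- tryCatch(
    fwnn_forward_matrix(p, x, aggregation)$prediction,
    fwnndmp_degenerate_activation = function(e) NULL
  )
  if (is.null(pred) || any(!is.finite(pred))) return(0)
  1 / (1 + mean((pred - y)^2))
}

# draw one random chromosome within the configured init ranges
random_chromosome <- function(n_inputs, n_rules, init_ranges) {
  k <- n_rules * n_inputs
  runif_in <- function(n, r) stats::runif(n, r[1], r[2])
  signed <- function(n, r) {
    runif_in(n, r) * sample(c(-1, 1), n, replace = TRUE)
  }
  c(runif_in(k, init_ranges$centers),
    signed(k, init_ranges$spreads),
    signed(k, init_ranges$dilations),
    runif_in(k, init_ranges$translations),
    runif_in(n_rules, init_ranges$weights))
}

# per-gene mutation sd: 10% of each group's init range width, laid out to
# match the chromosome
mutation_sd_vector <- function(n_inputs, n_rules, init_ranges) {
  k <- n_rules * n_inputs
  width <- function(r) 0.1 * (r[2] - r[1])
  c(rep(width(init_ranges$centers), k),
    rep(width(init_ranges$spreads), k),
    rep(width(init_ranges$dilations), k),
    rep(width(init_ranges$translations), k),
    rep(width(init_ranges$weights), n_rules))
}

#' Real-coded genetic algorithm over a fitness function
#'
#' Generic GA engine used for both the FWNN and the baseline perceptron:
#' tournament selection of size 2, arithmetic (blend) crossover applied with
#' probability `crossover_rate`, per-gene Gaussian mutation with probability
#' `mutation_rate`, and elitism. The best-so-far fitness trace is
#' non-decreasing by construction. Fully deterministic under a fixed seed.
#'
#' @param fitness_fn Function mapping a chromosome to a scalar fitness
#'   (higher is better).
#' @param init_fn Zero-argument function drawing one random chromosome.
#' @param config A [ga_config()].
#' @param mutation_sd Per-gene mutation standard deviations (recycled).
#' @return List with `best` (chromosome), `best_fitness`, and `trace`
#'   (best fitness per generation).
#' @export
ga_optimize <- function(fitness_fn, init_fn, config = ga_config(),
                        mutation_sd = 0.1) {
  if (!is.null(config$seed)) set.seed(config$seed)
  npop <- config$population_size
  pop <- lapply(seq_len(npop), function(i) init_fn())
  fit <- vapply(pop, fitness_fn, numeric(1))
  trace <- numeric(config$max_generations)
  for (gen in seq_len(config$max_generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite_idx <- ord[seq_len(min(config$elitism_count, npop))]
    newpop <- pop[elite_idx]
    while (length(newpop) < npop) {
      p1 <- pop[[tournament_pick(fit)]]
      p2 <- pop[[tournament_pick(fit)]]
      child <- if (stats::runif(1) < config$crossover_rate) {
        # blend (BLX-0.25) crossover: per-gene arithmetic mix extended 25%
        # beyond the parental interval, so crossover can explore outward
        alpha <- stats::runif(length(p1), -0.25, 1.25)
        alpha * p1 + (1 - alpha) * p2
      } else {
        p1
      }
      mut <- stats::runif(length(child)) < config$mutation_rate
      if (any(mut)) {
        sdv <- rep_len(mutation_sd, length(child))
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sdv[mut])
      }
      newpop[[length(newpop) + 1]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, fitness_fn, numeric(1))
    # elites are re-evaluated on the same data, so max fitness never drops
    trace[gen] <- max(fit)
  }
  best <- which.max(fit)
  list(best = pop[[best]], best_fitness = fit[best], trace = cummax(trace))
}

tournament_pick <- function(fit) {
  i <- sample.int(length(fit), 2, replace = TRUE)
  if (fit[i[1]] >= fit[i[2]]) i[1] else i[2]
}

#' GA stage for the FWNN
#'
#' Runs [ga_optimize()] with the FWNN chromosome encoding, fitness
#' `1/(1+MSE)` and initialization ranges from `config$init_ranges`.
#'
#' @param x Scaled input matrix; @param y scaled targets.
#' @param n_rules Number of fuzzy rules.
#' @param config A [ga_config()].
#' @param aggregation,wavelet Forward settings.
#' @return As [ga_optimize()].
#' @export
fwnn_ga_optimize <- function(x, y, n_rules, config = ga_config(),
                             aggregation = "normalized", wavelet = "mexhat") {
  x <- as.matrix(x)
  if (nrow(x) == 0) fwnn_stop("empty dataset", "fwnndmp_invalid_input")
  ga_optimize(
    fitness_fn = function(ch) {
      fwnn_fitness(ch, x, y, n_rules, aggregation, wavelet)
    },
    init_fn = function() {
      random_chromosome(ncol(x), n_rules, config$init_ranges)
    },
    config = config,
    mutation_sd = mutation_sd_vector(ncol(x), n_rules, config$init_ranges)
  )
}

#' Analytic gradient of the squared error for one sample
#'
#' Partial derivatives of \eqn{E = (\hat y - y)^2} with respect to every
#' center, spread, dilation, translation and weight, for the product
#' per-input wavelet combiner and either aggregation mode. Used by
#' [fwnn_gd_train()]; exposed for gradient checking against finite
#' differences.
#'
#' @param params An `fwnn_params` object.
#' @param x Scaled input vector.
#' @param y_target Scaled target value.
#' @return List with matrices `centers`, `spreads`, `dilations`,
#'   `translations` and vector `weights`, shaped like the parameters.
#' @export
fwnn_gradients <- function(params, x, y_target) {
  g <- fwnn_gradients_batch(params, matrix(x, nrow = 1), y_target)
  g
}

# batch gradient of mean((yhat - y)^2) over the rows of X; returns the
# gradient averaged over samples plus the batch mse
fwnn_gradients_batch <- function(params, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  R <- params$n_rules
  p <- params$n_inputs
  fw <- fwnn_forward_matrix(params, X, params$aggregation)
  mu <- fw$mu
  psihat <- fw$psihat
  yhat <- fw$prediction
  err <- yhat - y
  e <- 2 * err / n  # d(mean sq err)/d(yhat_s)

  if (params$aggregation == "normalized") {
    s <- rowSums(mu)
    dpsihat <- mu / s                       # n x R
    dmu <- (psihat - yhat) / s              # n x R
  } else {
    dpsihat <- mu
    dmu <- psihat
  }

  g_c <- matrix(0, R, p); g_s <- matrix(0, R, p)
  g_a <- matrix(0, R, p); g_b <- matrix(0, R, p)
  g_w <- numeric(R)

  for (j in seq_len(R)) {
    dx <- sweep(X, 2, params$centers[j, ], "-")          # n x p
    zm <- sweep(dx, 2, params$spreads[j, ], "/")
    z <- sweep(sweep(X, 2, params$translations[j, ], "-"),
               2, params$dilations[j, ], "/")
    psi <- mother_wavelet(z, params$wavelet)             # n x p
    psip <- mother_wavelet_deriv(z, params$wavelet)
    ej_mu <- e * dmu[, j] * mu[, j]                      # n
    ej_psi <- e * dpsihat[, j]                           # n

    prodpsi <- psi[, 1]
    if (p > 1) for (i in 2:p) prodpsi <- prodpsi * psi[, i]
    g_w[j] <- sum(ej_psi * prodpsi)

    for (i in seq_len(p)) {
      # membership partials: dmu/dc = mu (x-c)/sigma^2 ; dmu/dsigma = mu (x-c)^2/sigma^3
      g_c[j, i] <- sum(ej_mu * dx[, i] / params$spreads[j, i]^2)
      g_s[j, i] <- sum(ej_mu * zm[, i]^2 / params$spreads[j, i])
      # wavelet partials via leave-one-out product (robust at psi zeros)
      if (p > 1) {
        loo <- rep(1, n)
        for (k in seq_len(p)) if (k != i) loo <- loo * psi[, k]
      } else {
        loo <- rep(1, n)
      }
      t_ji <- params$weights[j] * loo * psip[, i]
      g_b[j, i] <- sum(ej_psi * t_ji * (-1 / params$dilations[j, i]))
      g_a[j, i] <- sum(ej_psi * t_ji * (-z[, i] / params$dilations[j, i]))
    }
  }
  list(centers = g_c, spreads = g_s, dilations = g_a,
       translations = g_b, weights = g_w, mse = mean(err^2))
}

# numeric gradient by central differences (gradient checking / fallback)
fwnn_gradients_numeric <- function(params, X, y, h = 1e-6) {
  X <- as.matrix(X)
  loss <- function(ch) {
    pp <- fwnn_decode(ch, params$n_inputs, params$n_rules,
                      aggregation = params$aggregation,
                      wavelet = params$wavelet)
    mean((fwnn_forward_matrix(pp, X, params$aggregation)$prediction - y)^2)
  }
  ch <- fwnn_encode(params)
  g <- numeric(length(ch))
  for (i in seq_along(ch)) {
    up <- ch; up[i] <- up[i] + h
    dn <- ch; dn[i] <- dn[i] - h
    g[i] <- (loss(up) - loss(dn)) / (2 * h)
  }
  g
}

#' Full-batch gradient descent refinement
#'
#' Plain gradient descent on the training MSE over all samples, starting
#' from the supplied parameters (typically the GA incumbent). Spreads and
#' dilations are kept away from zero (magnitude >= 1e-6) after each step.
#' The returned parameters are the best (lowest training MSE) visited,
#' including the starting point, so refinement never worsens the incumbent.
#'
#' A monotone-descent safeguard protects the fixed step size: a step that
#' increases the loss (or drives it non-finite) is rejected, the state
#' reverts to the best visited, and the learning rate is halved for the
#' remaining epochs (it never grows back). Descent steps are therefore
#' always plain gradient steps; the safeguard only ever shrinks them. A
#' run whose step underflows this way is aborted with a diagnostic naming
#' the epoch.
#'
#' @param params Starting `fwnn_params`.
#' @param x Scaled input matrix; @param y scaled targets.
#' @param config A [gd_config()].
#' @param update Parameter groups to update; the rest stay frozen (useful
#'   for diagnostics, e.g. weight-only refinement is an exactly quadratic
#'   problem).
#' @return List with `params` (refined), `trace` (training MSE after each
#'   epoch, preceded by the initial MSE), and `epochs_run`.
#' @export
fwnn_gd_train <- function(params, x, y, config = gd_config(),
                          update = c("centers", "spreads", "dilations",
                                     "translations", "weights")) {
  update <- match.arg(update, several.ok = TRUE)
  x <- as.matrix(x)
  lr <- config$learning_rate
  cur <- params
  g0 <- fwnn_gradients_batch(cur, x, y)
  best <- cur
  best_mse <- g0$mse
  trace <- numeric(0)
  epochs <- 0
  for (ep in seq_len(config$max_epochs)) {
    g <- if (config$gradient_mode == "analytic") {
      fwnn_gradients_batch(cur, x, y)
    } else {
      gd <- fwnn_gradients_numeric(cur, x, y)
      k <- cur$n_rules * cur$n_inputs
      list(centers = matrix(gd[1:k], cur$n_rules, byrow = TRUE),
           spreads = matrix(gd[(k + 1):(2 * k)], cur$n_rules, byrow = TRUE),
           dilations = matrix(gd[(2 * k + 1):(3 * k)], cur$n_rules, byrow = TRUE),
           translations = matrix(gd[(3 * k + 1):(4 * k)], cur$n_rules, byrow = TRUE),
           weights = gd[(4 * k + 1):(4 * k + cur$n_rules)],
           mse = mean((fwnn_forward_matrix(cur, x)$prediction - y)^2))
    }
    keep_away <- function(m) {
      small <- abs(m) < 1e-6
      m[small] <- ifelse(m[small] < 0, -1e-6, 1e-6)
      m
    }
    if ("centers" %in% update) cur$centers <- cur$centers - lr * g$centers
    if ("spreads" %in% update) {
      cur$spreads <- keep_away(cur$spreads - lr * g$spreads)
    }
    if ("dilations" %in% update) {
      cur$dilations <- keep_away(cur$dilations - lr * g$dilations)
    }
    if ("translations" %in% update) {
      cur$translations <- cur$translations - lr * g$translations
    }
    if ("weights" %in% update) cur$weights <- cur$weights - lr * g$weights
    mse <- tryCatch(
      mean((fwnn_forward_matrix(cur, x)$prediction - y)^2),
      fwnndmp_degenerate_activation = function(e) NaN
    )
    if (!is.finite(mse) || mse > best_mse) {
      diverged <- !is.finite(mse)
      # reject the step: restart from the incumbent with a halved step
      cur <- best
      lr <- lr / 2
      mse <- best_mse
      if (lr < config$learning_rate * 2^-40) {
        if (diverged) {
          fwnn_stop(
            sprintf("gradient descent diverged: non-finite loss at epoch %d", ep),
            "fwnndmp_divergence"
          )
        }
        trace <- c(trace, mse)
        epochs <- ep
        break  # step size exhausted at a stationary point
      }
    }
    trace <- c(trace, mse)
    epochs <- ep
    if (mse < best_mse) {
      best <- cur
      best_mse <- mse
    }
    if (mse <= config$target_error) break
  }
  list(params = best, trace = c(g0$mse, trace), epochs_run = epochs,
       final_mse = best_mse)
}

#' Hybrid GA + gradient-descent training of the FWNN
#'
#' The two-stage scheme: a real-coded GA globally searches all five
#' parameter groups (centers, spreads, dilations, translations, weights);
#' the best chromosome is then refined by full-batch gradient descent.
#' Metrics are computed on the training split and, when supplied, the test
#' split, in scaled target units.
#'
#' @param x_train,y_train Scaled training inputs (matrix) and targets.
#' @param x_test,y_test Optional scaled test split.
#' @param n_rules Number of fuzzy rules (the full A/A/O model uses 8).
#' @param ga A [ga_config()]; @param gd a [gd_config()].
#' @param aggregation,wavelet Forward settings.
#' @param seed RNG seed for the whole run; identical seeds reproduce
#'   bit-identical reports.
#' @return A list of class `training_report`: `ga_best_fitness_per_generation`,
#'   `gd_train_mse_per_epoch`, `final_params`, `train_metrics`,
#'   `test_metrics`, `seed`.
#' @export
fwnn_hybrid_train <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                              n_rules = 8, ga = ga_config(), gd = gd_config(),
                              aggregation = "normalized", wavelet = "mexhat",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_train <- as.matrix(x_train)
  ga_res <- fwnn_ga_optimize(x_train, y_train, n_rules,
                             config = ga, aggregation = aggregation,
                             wavelet = wavelet)
  start <- fwnn_decode(ga_res$best, ncol(x_train), n_rules,
                       aggregation = aggregation, wavelet = wavelet)
  gd_res <- fwnn_gd_train(start, x_train, y_train, config = gd)
  final <- gd_res$params
  train_pred <- fwnn_predict(final, x_train)
  train_metrics <- compute_metrics(y_train, train_pred)
  test_metrics <- NULL
  if (!is.null(x_test)) {
    test_pred <- fwnn_predict(final, as.matrix(x_test))
    test_metrics <- compute_metrics(y_test, test_pred)
  }
  structure(
    list(ga_best_fitness_per_generation = ga_res$trace,
         gd_train_mse_per_epoch = gd_res$trace,
         final_params = final,
         train_metrics = train_metrics, test_metrics = test_metrics,
         seed = seed, model = "fwnn"),
    class = "training_report"
  )
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("Training report (%s)\n", x$model))
  if (length(x$ga_best_fitness_per_generation)) {
    cat(sprintf("  GA: %d generations, final best fitness %.6f\n",
                length(x$ga_best_fitness_per_generation),
                x$ga_best_fitness_per_generation[length(x$ga_best_fitness_per_generation)]))
  }
  if (length(x$gd_train_mse_per_epoch)) {
    cat(sprintf("  GD: %d epochs, train MSE %.6g -> %.6g\n",
                length(x$gd_train_mse_per_epoch) - 1,
                x$gd_train_mse_per_epoch[1],
                min(x$gd_train_mse_per_epoch)))
  }
  cat("  train: "); print(x$train_metrics)
  if (!is.null(x$test_metrics)) { cat("  test:  "); print(x$test_metrics) }
  invisible(x)
}

#' Serialize a training report to JSON
#'
#' @param report A `training_report`.
#' @param path Output path.
#' @export
write_training_report <- function(report, path) {
  out <- list(
    model = report$model,
    seed = report$seed,
    ga_best_fitness_per_generation = report$ga_best_fitness_per_generation,
    gd_train_mse_per_epoch = report$gd_train_mse_per_epoch,
    train_metrics = unclass(report$train_metrics),
    test_metrics = if (!is.null(report$test_metrics)) unclass(report$test_metrics)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
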