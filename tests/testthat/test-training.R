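test_that("chromosome encoding is an exact inverse pair with the fixed layout", {
  p <- toy_fwnn()
  ch <- fwnn_encode(p)
  expect_length(ch, 2 * (4 * 2) + 2)
  q <- fwnn_decode(ch, 2, 2)
  expect_identical(fwnn_encode(q), ch)
  # reference calibration round-trips bit-identically
  ref <- reference_fwnn_params()
  back <- fwnn_decode(fwnn_encode(ref), 5, 8)
  expect_identical(back$centers, ref$centers)
  expect_identical(back$spreads, ref$spreads)
  expect_identical(back$dilations, ref$dilations)
  expect_identical(back$translations, ref$translations)
  expect_identical(back$weights, ref$weights)
  # decode clamps near-zero divisors away from zero
  ch0 <- fwnn_encode(p)
  ch0[5] <- 1e-9  # first spread gene (after the 4 center genes)
  q0 <- fwnn_decode(ch0, 2, 2)
  expect_equal(q0$spreads[1, 1], 1e-6)
  expect_error(fwnn_decode(ch[-1], 2, 2), class = "fwnndmp_schema_error")
})

test_that("fitness is 1/(1+MSE) and degrades to 0 on degenerate activation", {
  set.seed(21)
  p <- toy_fwnn()
  X <- matrix(runif(40, -1, 1), 20, 2)
  y <- fwnn_predict(p, X)
  ch <- fwnn_encode(p)
  expect_equal(fwnn_fitness(ch, X, y, 2), 1)          # perfect predictor
  expect_equal(fwnn_fitness(ch, X, y + sqrt(1), 2), 0.5, tolerance = 1e-12)
  # compose independently: random chromosome vs batch_predict + mse
  ch2 <- ch + rnorm(length(ch), 0, 0.3)
  p2 <- fwnn_decode(ch2, 2, 2)
  mse <- mean((fwnn_predict(p2, X) - y)^2)
  expect_equal(fwnn_fitness(ch2, X, y, 2), 1 / (1 + mse), tolerance = 1e-12)
  # chromosome whose rules cannot fire anywhere near the data
  ch3 <- ch
  ch3[1:4] <- 1e3     # centers far away
  ch3[5:8] <- 1e-6    # minuscule spreads
  expect_equal(fwnn_fitness(ch3, X, y, 2), 0)
})

test_that("GA respects elitism, determinism, and no-variation stasis", {
  set.seed(31)
  p <- toy_fwnn()
  X <- matrix(runif(30, -1, 1), 15, 2)
  y <- fwnn_predict(p, X) + rnorm(15, 0, 0.05)
  cfg <- ga_config(population_size = 12, max_generations = 15, seed = 42)
  run1 <- fwnn_ga_optimize(X, y, 2, cfg)
  run2 <- fwnn_ga_optimize(X, y, 2, cfg)
  expect_identical(run1$best, run2$best)            # bit-identical under seed
  expect_identical(run1$trace, run2$trace)
  expect_true(all(diff(run1$trace) >= 0))           # elitism guarantee
  expect_gte(run1$trace[length(run1$trace)], run1$trace[1])

  # Pc = 0, Pm = 0: population can only be reshuffled, best never changes
  cfg0 <- ga_config(population_size = 6, crossover_rate = 0,
                    mutation_rate = 0, max_generations = 10, seed = 7)
  fit_fn <- function(ch) fwnn_fitness(ch, X, y, 2)
  set.seed(7)
  init_pool <- replicate(6, random_chromosome_for_test(2, 2), simplify = FALSE)
  k <- 0
  run0 <- ga_optimize(fit_fn,
                      init_fn = function() {
                        k <<- k + 1
                        init_pool[[k]]
                      },
                      config = cfg0)
  expect_equal(run0$best_fitness, max(vapply(init_pool, fit_fn, numeric(1))))
})

test_that("analytic gradients match central finite differences", {
  set.seed(17)
  for (agg in c("normalized", "sum")) {
    for (rep in 1:20) {
      p <- random_fwnn(sample(2:4, 1), sample(2:3, 1), aggregation = agg)
      X <- matrix(runif(3 * p$n_inputs, -1, 1), 3, p$n_inputs)
      y <- runif(3, -1, 1)
      g <- fwnndmp:::fwnn_gradients_batch(p, X, y)
      ga <- c(as.vector(t(g$centers)), as.vector(t(g$spreads)),
              as.vector(t(g$dilations)), as.vector(t(g$translations)),
              g$weights)
      gn <- fwnndmp:::fwnn_gradients_numeric(p, X, y)
      denom <- pmax(abs(gn), 1e-4)
      expect_lt(max(abs(ga - gn) / denom), 1e-5)
    }
  }
})

test_that("single-sample gradient vanishes at a perfect fit and is linear in w", {
  p <- toy_fwnn()
  x <- c(0.2, -0.3)
  y <- fwnn_forward(p, x)$output
  g <- fwnn_gradients(p, x, y)
  expect_equal(max(abs(unlist(g[c("centers", "spreads", "dilations",
                                  "translations", "weights")]))), 0)
  # dE/dw_j = 2 (yhat - y) mu_j prod(psi) / sum(mu) in normalized mode
  y2 <- y - 0.37
  g2 <- fwnn_gradients(p, x, y2)
  tr <- fwnn_forward(p, x)
  prodpsi <- tr$wavelet_outputs / p$weights
  expected <- 2 * (tr$output - y2) * tr$firing_strengths * prodpsi /
    sum(tr$firing_strengths)
  expect_equal(g2$weights, expected, tolerance = 1e-12)
})

test_that("gradient descent refines without worsening and honors its limits", {
  set.seed(23)
  teacher <- toy_fwnn()
  data <- generate_teacher_data(teacher, 60, noise_sd = 0, seed = 5)
  start <- random_fwnn(2, 2)

  # learning_rate -> 0: parameters unchanged, flat trace
  res0 <- fwnn_gd_train(start, data$x, data$y,
                        gd_config(learning_rate = 1e-300, max_epochs = 5,
                                  target_error = 0))
  expect_equal(res0$params$centers, start$centers)
  expect_equal(diff(res0$trace), rep(0, 5), tolerance = 1e-12)

  # small lr on smooth data: monotone decreasing loss over early epochs
  res <- fwnn_gd_train(start, data$x, data$y,
                       gd_config(learning_rate = 1e-3, max_epochs = 50,
                                 target_error = 0))
  expect_true(all(diff(res$trace[1:25]) <= 1e-12))
  expect_lte(res$final_mse, res$trace[1])
})

test_that("weight-only descent reaches the least-squares consequents", {
  # freeze antecedents/wavelets by matching teacher and student everywhere
  # except the weights: the loss is then quadratic in w with closed form
  set.seed(29)
  teacher <- toy_fwnn()
  data <- generate_teacher_data(teacher, 80, noise_sd = 0, seed = 9)
  fw <- fwnndmp:::fwnn_forward_matrix(teacher, data$x, "normalized")
  # design matrix of per-rule activations: yhat = A w
  A <- (fw$mu / rowSums(fw$mu)) * (fw$psihat / rep(teacher$weights,
                                                   each = nrow(data$x)))
  w_ls <- qr.solve(A, data$y)
  start <- teacher
  start$weights <- c(0, 0)
  res <- fwnn_gd_train(start, data$x, data$y,
                       gd_config(learning_rate = 0.15, max_epochs = 4000,
                                 target_error = 1e-14),
                       update = "weights")
  expect_equal(res$params$weights, as.numeric(w_ls), tolerance = 1e-3)
  expect_lt(res$final_mse, 1e-7)
})

test_that("hybrid training is deterministic and the GD stage keeps the GA incumbent", {
  set.seed(37)
  teacher <- toy_fwnn()
  data <- generate_teacher_data(teacher, 60, noise_sd = 0.05, seed = 13)
  ga <- ga_config(population_size = 10, max_generations = 8)
  gd <- gd_config(learning_rate = 1e-3, max_epochs = 30)
  r1 <- fwnn_hybrid_train(data$x, data$y, n_rules = 2, ga = ga, gd = gd,
                          seed = 99)
  r2 <- fwnn_hybrid_train(data$x, data$y, n_rules = 2, ga = ga, gd = gd,
                          seed = 99)
  expect_identical(r1$final_params$weights, r2$final_params$weights)
  expect_identical(r1$ga_best_fitness_per_generation,
                   r2$ga_best_fitness_per_generation)
  expect_identical(r1$gd_train_mse_per_epoch, r2$gd_train_mse_per_epoch)
  # refined training MSE never exceeds the GA incumbent's
  expect_lte(min(r1$gd_train_mse_per_epoch),
             r1$gd_train_mse_per_epoch[1] + 1e-15)
  expect_lte(r1$train_metrics$mse, r1$gd_train_mse_per_epoch[1] + 1e-12)
})

test_that("hybrid training beats either stage alone on most seeds", {
  teacher <- make_teacher_fwnn(2, 2, seed = 3)
  data <- generate_teacher_data(teacher, 120, noise_sd = 0, seed = 3)
  ga <- ga_config(population_size = 20, max_generations = 25)
  gd <- gd_config(learning_rate = 0.5, max_epochs = 150, target_error = 0)
  wins <- 0
  for (seed in 1:10) {
    hyb <- fwnn_hybrid_train(data$x, data$y, n_rules = 2, ga = ga, gd = gd,
                             seed = seed)
    set.seed(seed)
    ga_only <- fwnn_ga_optimize(data$x, data$y, 2, ga)
    ga_mse <- 1 / ga_only$best_fitness - 1
    set.seed(seed + 1000)
    rand_start <- fwnn_decode(
      fwnndmp:::random_chromosome(2, 2, ga$init_ranges), 2, 2)
    gd_only <- fwnn_gd_train(rand_start, data$x, data$y, gd)
    if (hyb$train_metrics$mse <= min(ga_mse, gd_only$final_mse) + 1e-12) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 8)
})

test_that("a 1-rule student with the teacher's own parameters is exact", {
  teacher <- make_teacher_fwnn(1, 3, seed = 4)
  data <- generate_teacher_data(teacher, 50, noise_sd = 0, seed = 4)
  expect_equal(fwnn_predict(teacher, data$x), data$y, tolerance = 1e-15)
  m <- compute_metrics(data$y, fwnn_predict(teacher, data$x))
  expect_equal(m$rmse, 0)
})
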