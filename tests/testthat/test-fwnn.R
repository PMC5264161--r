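test_that("Gaussian membership matches its closed form and peaks at the center", {
  expect_equal(gaussian_membership(0.5, 0.5, 1.2), 1.0)
  expect_equal(gaussian_membership(1, 0, 1), exp(-0.5))
  # strictly decreasing in |x - c|
  d <- gaussian_membership(c(0.1, 0.5, 1.3), 0, 1)
  expect_true(all(diff(d) < 0))
  # spread enters squared: reference-calibration pair, sign flipped
  xs <- seq(-2, 2, length.out = 7)
  expect_identical(gaussian_membership(xs, -1.8480, -0.2853),
                   gaussian_membership(xs, -1.8480, 0.2853))
  expect_error(gaussian_membership(1, 0, 0), class = "fwnndmp_invalid_parameter")
})

test_that("rule firing strength is the product of memberships", {
  expect_equal(rule_strength(rep(1, 5)), 1)
  expect_equal(rule_strength(c(0.5, 0.5)), 0.25)
  set.seed(7)
  m <- runif(5, 0.01, 1)
  loop <- 1
  for (v in m) loop <- loop * v
  expect_equal(rule_strength(m), loop, tolerance = 1e-12)
  expect_error(rule_strength(numeric(0)), class = "fwnndmp_invalid_input")
})

test_that("mother wavelets satisfy their defining values and symmetry", {
  expect_equal(mother_wavelet(0), 1)
  expect_equal(mother_wavelet(1), 0)
  expect_equal(mother_wavelet(-1), 0)
  expect_equal(mother_wavelet(2), -3 * exp(-2))
  expect_equal(mother_wavelet(0, "morlet"), 1)
  z <- seq(0.1, 4, by = 0.3)
  expect_equal(mother_wavelet(z), mother_wavelet(-z))
  expect_equal(mother_wavelet(z, "morlet"), mother_wavelet(-z, "morlet"))
  expect_lt(abs(mother_wavelet(12)), 1e-20)
})

test_that("wavelet neuron combines per-input wavelets by product", {
  # x at the translations: psi(0) = 1 everywhere, output = weight
  expect_equal(wavelet_neuron(c(0.3, -0.2), c(1.1, 0.7), c(0.3, -0.2), 2), 2)
  # one input at |z| = 1 annihilates the product
  expect_equal(wavelet_neuron(c(1.7, 99), c(1, 3), c(0.7, 1), 5), 0)
  # reference-calibration rule 1 against the scalar loop oracle
  p <- reference_fwnn_params()
  x <- c(0.2, -0.3, 0.1, 0.4, -0.1)
  loop <- p$weights[1]
  for (i in 1:5) {
    loop <- loop * ref_mexhat((x[i] - p$translations[1, i]) / p$dilations[1, i])
  }
  expect_equal(wavelet_neuron(x, p$dilations[1, ], p$translations[1, ],
                              p$weights[1]),
               loop, tolerance = 1e-10)
  expect_error(wavelet_neuron(c(0, 0), c(0, 1), c(0, 0), 1),
               class = "fwnndmp_invalid_parameter")
})

test_that("forward pass reduces correctly in degenerate single-rule geometry", {
  p1 <- fwnn_params(
    centers = matrix(c(0.2, -0.1), 1, 2),
    spreads = matrix(1, 1, 2),
    dilations = matrix(1, 1, 2),
    translations = matrix(c(0.2, -0.1), 1, 2),
    weights = 3
  )
  # x at the rule's centers and translations: mu = 1, psihat = 3
  expect_equal(fwnn_forward(p1, c(0.2, -0.1))$output, 3)
  expect_equal(fwnn_forward(p1, c(0.2, -0.1), aggregation = "sum")$output, 3)
  # all rules sharing the same consequent: normalized output is that constant
  pk <- toy_fwnn()
  pk$weights <- c(2, 2)
  pk$dilations[] <- 1e6  # z ~ 0 for any probe: psi ~ 1, psihat ~ w
  for (x in list(c(0, 0), c(0.7, -0.3), c(-1, 1))) {
    expect_equal(fwnn_forward(pk, x)$output, 2, tolerance = 1e-8)
  }
})

test_that("forward trace is internally consistent and bounded", {
  set.seed(11)
  for (rep in 1:25) {
    p <- random_fwnn(n_rules = sample(2:6, 1), n_inputs = sample(2:5, 1))
    x <- runif(p$n_inputs, -1.5, 1.5)
    tr <- fwnn_forward(p, x)
    expect_true(all(tr$memberships > 0 & tr$memberships <= 1))
    expect_true(all(tr$firing_strengths > 0 & tr$firing_strengths <= 1))
    expect_equal(tr$firing_strengths, apply(tr$memberships, 1, prod),
                 tolerance = 1e-12)
    # normalized output is a convex combination of the consequents
    expect_gte(tr$output, min(tr$wavelet_outputs) - 1e-12)
    expect_lte(tr$output, max(tr$wavelet_outputs) + 1e-12)
  }
})

test_that("vectorized forward agrees with the scalar loop oracle", {
  set.seed(42)
  for (rep in 1:200) {
    agg <- sample(c("normalized", "sum"), 1)
    wav <- sample(c("mexhat", "morlet"), 1)
    p <- random_fwnn(sample(1:6, 1), sample(1:5, 1), agg, wav)
    x <- runif(p$n_inputs, -2, 2)
    expect_equal(fwnn_forward(p, x)$output, ref_forward(p, x),
                 tolerance = 1e-10)
  }
  # packaged reference calibration on fixed probes
  p <- reference_fwnn_params()
  for (x in list(rep(0, 5), c(0.5, -0.5, 0.2, 0.1, -0.3), rep(-0.9, 5))) {
    expect_equal(fwnn_forward(p, x)$output, ref_forward(p, x),
                 tolerance = 1e-10)
  }
})

test_that("flipping spread or dilation signs leaves the output unchanged", {
  set.seed(5)
  p <- random_fwnn(4, 3)
  x <- runif(3, -1, 1)
  base <- fwnn_forward(p, x)$output
  p2 <- p
  p2$spreads[2, 1] <- -p2$spreads[2, 1]
  p2$dilations[3, 2] <- -p2$dilations[3, 2]
  expect_equal(fwnn_forward(p2, x)$output, base, tolerance = 1e-14)
})

test_that("forward output is continuous in the input", {
  p <- reference_fwnn_params()
  x <- c(0.1, -0.2, 0.3, 0.05, -0.1)
  y0 <- fwnn_forward(p, x)$output
  y1 <- fwnn_forward(p, x + 1e-8)$output
  expect_lt(abs(y1 - y0), 1e-6)
})

test_that("batch prediction equals per-sample forward calls", {
  p <- toy_fwnn()
  expect_identical(fwnn_predict(p, matrix(numeric(0), 0, 2)), numeric(0))
  x1 <- matrix(c(0.3, -0.4), 1, 2)
  expect_equal(fwnn_predict(p, x1), fwnn_forward(p, x1[1, ])$output)
  set.seed(3)
  X <- matrix(runif(70, -1, 1), 35, 2)
  loop <- vapply(1:35, function(i) fwnn_forward(p, X[i, ])$output, numeric(1))
  expect_equal(fwnn_predict(p, X), loop, tolerance = 1e-12)
  expect_error(fwnn_predict(p, matrix(0, 2, 3)), class = "fwnndmp_schema_error")
})

test_that("degenerate activation raises a dedicated error", {
  p <- toy_fwnn()
  p$spreads[] <- 1e-3
  expect_error(fwnn_forward(p, c(50, 50)),
               class = "fwnndmp_degenerate_activation")
  # sum mode has no normalization, so it stays finite
  expect_equal(fwnn_forward(p, c(50, 50), aggregation = "sum")$output, 0)
})

test_that("parameter validation names the offending entry", {
  expect_error(
    fwnn_params(matrix(0, 2, 2), matrix(c(1, 0, 1, 1), 2, 2),
                matrix(1, 2, 2), matrix(0, 2, 2), c(1, 1)),
    "rule 2, input 1"
  )
  expect_error(
    fwnn_params(matrix(0, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2),
                matrix(0, 2, 2), c(1, 2, 3)),
    class = "fwnndmp_invalid_parameter"
  )
})

test_that("parameter files round-trip through JSON", {
  p <- reference_fwnn_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_fwnn_params(p, path)
  q <- read_fwnn_params(path)
  expect_equal(q$centers, p$centers)
  expect_equal(q$spreads, p$spreads)
  expect_equal(q$dilations, p$dilations)
  expect_equal(q$translations, p$translations)
  expect_equal(q$weights, p$weights)
  expect_identical(q$input_names, c("pH", "DMP_in", "DO", "ORP", "MLSS"))
})
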