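# Deliberately naive scalar reference implementations, kept independent of
# the package's vectorized code paths, plus small fixture builders.

ref_mexhat <- function(z) (1 - z^2) * exp(-z^2 / 2)
ref_morlet <- function(z) cos(5 * z) * exp(-z^2 / 2)

# plain-loop forward pass: one scalar operation at a time
ref_forward <- function(params, x, aggregation = params$aggregation) {
  wave <- if (params$wavelet == "mexhat") ref_mexhat else ref_morlet
  R <- params$n_rules
  p <- params$n_inputs
  mu <- numeric(R)
  psihat <- numeric(R)
  for (j in 1:R) {
    m <- 1
    for (i in 1:p) {
      f <- exp(-(x[i] - params$centers[j, i])^2 /
                 (2 * params$spreads[j, i]^2))
      m <- m * f
    }
    mu[j] <- m
    w <- 1
    for (i in 1:p) {
      z <- (x[i] - params$translations[j, i]) / params$dilations[j, i]
      w <- w * wave(z)
    }
    psihat[j] <- params$weights[j] * w
  }
  if (aggregation == "normalized") {
    sum(mu * psihat) / sum(mu)
  } else {
    sum(mu * psihat)
  }
}

# random but well-conditioned parameter draw for property tests
random_fwnn <- function(n_rules, n_inputs, aggregation = "normalized",
                        wavelet = "mexhat") {
  k <- n_rules * n_inputs
  fwnn_params(
    centers = matrix(runif(k, -1.5, 1.5), n_rules, n_inputs),
    spreads = matrix(runif(k, 0.3, 2.5) * sample(c(-1, 1), k, TRUE),
                     n_rules, n_inputs),
    dilations = matrix(runif(k, 0.3, 2.5) * sample(c(-1, 1), k, TRUE),
                       n_rules, n_inputs),
    translations = matrix(runif(k, -1.5, 1.5), n_rules, n_inputs),
    weights = runif(n_rules, -2, 2),
    aggregation = aggregation, wavelet = wavelet
  )
}

# tiny two-rule, two-input network with friendly geometry
toy_fwnn <- function(aggregation = "normalized") {
  fwnn_params(
    centers = matrix(c(-0.5, -0.5, 0.5, 0.5), 2, 2, byrow = TRUE),
    spreads = matrix(0.8, 2, 2),
    dilations = matrix(c(1.2, 0.9, 1.1, 1.4), 2, 2, byrow = TRUE),
    translations = matrix(c(-0.4, -0.6, 0.5, 0.3), 2, 2, byrow = TRUE),
    weights = c(1.5, -0.8),
    aggregation = aggregation
  )
}

process_columns_for_test <- function() {
  c("pH", "DMP_in", "DO", "ORP", "MLSS", "DMP_eff")
}

# draw a raw chromosome matching the package's init-range defaults
random_chromosome_for_test <- function(n_rules, n_inputs) {
  k <- n_rules * n_inputs
  c(runif(k, -2, 2),
    runif(k, 0.1, 3) * sample(c(-1, 1), k, TRUE),
    runif(k, 0.1, 3) * sample(c(-1, 1), k, TRUE),
    runif(k, -2, 2),
    runif(n_rules, -3, 3))
}

# well-formed process data frame without going through the generator
toy_process_df <- function(n = 10) {
  data.frame(
    pH = seq(6.8, 7.8, length.out = n),
    DMP_in = seq(30, 80, length.out = n),
    DO = seq(2.6, 5.7, length.out = n),
    ORP = seq(-200, 100, length.out = n),
    MLSS = seq(2800, 3200, length.out = n),
    DMP_eff = seq(5, 18, length.out = n)
  )
}
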