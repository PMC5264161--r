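#' Gaussian membership function
#'
#' Degree of membership of a scaled input value in a fuzzy set with Gaussian
#' shape: \eqn{\exp(-(x-c)^2 / (2\sigma^2))}. The value is 1 exactly at the
#' center and strictly decreasing in \eqn{|x-c|}. The spread enters squared,
#' so its sign is irrelevant; it must be non-zero.
#'
#' @param x Input value(s), scaled units.
#' @param center Gaussian center \eqn{c}.
#' @param spread Gaussian spread \eqn{\sigma}, non-zero.
#' @return Membership value(s) in \eqn{(0, 1]}.
#' @export
gaussian_membership <- function(x, center, spread) {
  if (any(spread == 0)) {
    fwnn_stop("Gaussian spread must be non-zero", "fwnndmp_invalid_parameter")
  }
  exp(-((x - center)^2) / (2 * spread^2))
}

#' Rule firing strength (product AND)
#'
#' Combines per-input memberships of one rule into its firing strength using
#' multiplication as the AND operator.
#'
#' @param memberships Numeric vector of memberships in \eqn{(0, 1]}, one per
#'   input.
#' @return The product, in \eqn{(0, 1]} (possibly underflowing to 0 for
#'   far-out probes).
#' @export
rule_strength <- function(memberships) {
  if (length(memberships) == 0) {
    fwnn_stop("empty membership vector", "fwnndmp_invalid_input")
  }
  prod(memberships)
}

#' Mother wavelet
#'
#' The wavelet used as consequent activation. Default is the Mexican hat
#' \eqn{\psi(z) = (1 - z^2)\exp(-z^2/2)} (second derivative of a Gaussian);
#' a Morlet-style alternative \eqn{\cos(5z)\exp(-z^2/2)} is available. Both
#' are even, equal 1 at \eqn{z = 0}, and vanish as \eqn{|z| \to \infty}.
#'
#' @param z Dimensionless argument \eqn{(x - b)/a}.
#' @param family `"mexhat"` or `"morlet"`.
#' @return Wavelet value(s).
#' @export
mother_wavelet <- function(z, family = c("mexhat", "morlet")) {
  family <- match.arg(family)
  switch(family,
    mexhat = (1 - z^2) * exp(-z^2 / 2),
    morlet = cos(5 * z) * exp(-z^2 / 2)
  )
}

# derivative of the mother wavelet wrt z (needed for gradient training)
mother_wavelet_deriv <- function(z, family = c("mexhat", "morlet")) {
  family <- match.arg(family)
  switch(family,
    mexhat = z * (z^2 - 3) * exp(-z^2 / 2),
    morlet = -(5 * sin(5 * z) + z * cos(5 * z)) * exp(-z^2 / 2)
  )
}

#' Wavelet neuron output for one rule
#'
#' Computes the consequent of rule \eqn{j}:
#' \eqn{\hat\psi_j = w_j \prod_i \psi((x_i - b_{ji}) / a_{ji})},
#' the weighted product of per-input dilated/translated mother wavelets.
#'
#' @param x Scaled input vector.
#' @param dilations Dilation (scale) parameters \eqn{a_{ji}}, non-zero, one
#'   per input.
#' @param translations Translation (shift) parameters \eqn{b_{ji}}.
#' @param weight Consequent weight \eqn{w_j}.
#' @param family Mother wavelet family, see [mother_wavelet()].
#' @return Signed scalar \eqn{\hat\psi_j}.
#' @export
wavelet_neuron <- function(x, dilations, translations, weight,
                           family = c("mexhat", "morlet")) {
  family <- match.arg(family)
  if (any(dilations == 0)) {
    fwnn_stop("wavelet dilation must be non-zero", "fwnndmp_invalid_parameter")
  }
  z <- (x - translations) / dilations
  weight * prod(mother_wavelet(z, family))
}

#' FWNN forward pass for a single input vector
#'
#' Runs the five-layer network: fuzzification of each input through Gaussian
#' membership functions (layer 2), product AND over inputs to get per-rule
#' firing strengths (layer 3), wavelet-neuron consequents (layer 4), and
#' output aggregation (layer 5). In `"normalized"` mode the output is the
#' firing-strength-weighted average of the consequents,
#' \eqn{\sum_j \mu_j \hat\psi_j / \sum_j \mu_j}; in `"sum"` mode the plain
#' sum \eqn{\sum_j \mu_j \hat\psi_j}.
#'
#' @param params An `fwnn_params` object.
#' @param x Scaled input vector of length `n_inputs`.
#' @param aggregation Override for the aggregation mode stored in `params`.
#' @return A list of class `fwnn_trace` with elements `memberships`
#'   (`n_rules x n_inputs` matrix), `firing_strengths`, `wavelet_outputs`
#'   (per-rule vectors) and `output` (the scalar prediction in scaled
#'   target units).
#' @export
fwnn_forward <- function(params, x, aggregation = NULL) {
  validate_fwnn_params(params)
  if (length(x) != params$n_inputs) {
    fwnn_stop(sprintf("input vector has %d entries, expected %d",
                      length(x), params$n_inputs),
              "fwnndmp_schema_error")
  }
  if (is.null(aggregation)) aggregation <- params$aggregation
  aggregation <- match.arg(aggregation, c("normalized", "sum"))

  xr <- matrix(x, nrow = params$n_rules, ncol = params$n_inputs, byrow = TRUE)
  memberships <- exp(-((xr - params$centers)^2) / (2 * params$spreads^2))
  mu <- apply(memberships, 1, prod)

  z <- (xr - params$translations) / params$dilations
  psi <- mother_wavelet(z, params$wavelet)
  psihat <- params$weights * apply(psi, 1, prod)

  if (aggregation == "normalized") {
    s <- sum(mu)
    if (s < 1e-300) {
      fwnn_stop(
        "degenerate activation: no rule fires at this input (sum of firing strengths underflows); the probe lies outside the fuzzified region",
        "fwnndmp_degenerate_activation"
      )
    }
    output <- sum(mu * psihat) / s
  } else {
    output <- sum(mu * psihat)
  }

  structure(
    list(memberships = memberships, firing_strengths = mu,
         wavelet_outputs = psihat, output = output,
         aggregation = aggregation),
    class = "fwnn_trace"
  )
}

# vectorized forward over the rows of a scaled input matrix X (n x p).
# Returns list(mu, psihat, prediction): mu and psihat are n x n_rules.
fwnn_forward_matrix <- function(params, X, aggregation = NULL) {
  if (is.null(aggregation)) aggregation <- params$aggregation
  n <- nrow(X)
  R <- params$n_rules
  mu <- matrix(0, n, R)
  psihat <- matrix(0, n, R)
  for (j in seq_len(R)) {
    d <- sweep(X, 2, params$centers[j, ], "-")
    mu[, j] <- exp(-0.5 * rowSums(sweep(d, 2, params$spreads[j, ], "/")^2))
    z <- sweep(sweep(X, 2, params$translations[j, ], "-"),
               2, params$dilations[j, ], "/")
    psi <- mother_wavelet(z, params$wavelet)
    prodpsi <- psi[, 1]
    if (ncol(psi) > 1) for (i in 2:ncol(psi)) prodpsi <- prodpsi * psi[, i]
    psihat[, j] <- params$weights[j] * prodpsi
  }
  if (aggregation == "normalized") {
    s <- rowSums(mu)
    if (!all(is.finite(s)) || any(s < 1e-300)) {
      bad <- which(!is.finite(s) | s < 1e-300)[1]
      fwnn_stop(
        sprintf("degenerate activation: no rule fires for sample %d", bad),
        "fwnndmp_degenerate_activation"
      )
    }
    pred <- rowSums(mu * psihat) / s
  } else {
    pred <- rowSums(mu * psihat)
  }
  list(mu = mu, psihat = psihat, prediction = pred)
}

#' Batch prediction over a dataset
#'
#' Applies the FWNN forward pass to every row of a scaled input matrix or
#' data frame. Rows must be in the same scaled space (same [scaling_spec])
#' used when the parameters were trained.
#'
#' @param params An `fwnn_params` object.
#' @param newdata Matrix or data frame with `n_inputs` columns of scaled
#'   inputs (a `DMP_eff` column, if present, is dropped).
#' @param aggregation Optional aggregation override.
#' @return Numeric vector of predictions, one per row (scaled target units).
#' @export
fwnn_predict <- function(params, newdata, aggregation = NULL) {
  validate_fwnn_params(params)
  X <- newdata
  if (is.data.frame(X)) {
    X <- X[, setdiff(colnames(X), "DMP_eff"), drop = FALSE]
    X <- as.matrix(X)
  }
  if (length(X) == 0 || nrow(X) == 0) return(numeric(0))
  if (ncol(X) != params$n_inputs) {
    fwnn_stop(sprintf("newdata has %d columns, expected %d",
                      ncol(X), params$n_inputs),
              "fwnndmp_schema_error")
  }
  fwnn_forward_matrix(params, X, aggregation)$prediction
}

#' @export
predict.fwnn_params <- function(object, newdata, ...) {
  fwnn_predict(object, newdata)
}
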