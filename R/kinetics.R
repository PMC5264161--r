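#' Zone kinetic parameters for DMP hydrolysis
#'
#' The ASM2-style hydrolysis parameterization for one redox zone: maximum
#' specific hydrolysis rate constant `K`, half-saturation coefficient `Ks`
#' (in the units of the substrate-to-biomass ratio), hydrolysis reduction
#' factor `eta` (1 for the aerobic zone by convention), and the oxygen /
#' nitrate switching coefficients.
#'
#' @param zone One of `"anaerobic"`, `"anoxic"`, `"aerobic"`.
#' @param K Maximum specific hydrolysis rate (> 0, internal time units).
#' @param Ks Half-saturation coefficient (> 0).
#' @param eta Reduction factor in `(0, 1]`.
#' @param K_O2,K_NO3 Switching (saturation/inhibition) coefficients,
#'   mg L^-1; ASM2-conventional default 0.2.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(zone = c("aerobic", "anaerobic", "anoxic"),
                           K, Ks, eta = 1, K_O2 = 0.2, K_NO3 = 0.2) {
  zone <- match.arg(zone)
  if (K <= 0 || Ks <= 0) {
    fwnn_stop("K and Ks must be positive", "fwnndmp_invalid_parameter")
  }
  if (eta <= 0 || eta > 1) {
    fwnn_stop("eta must lie in (0, 1]", "fwnndmp_invalid_parameter")
  }
  if (K_O2 <= 0 || K_NO3 <= 0) {
    fwnn_stop("switching coefficients must be positive",
              "fwnndmp_invalid_parameter")
  }
  structure(list(zone = zone, K = K, Ks = Ks, eta = eta,
                 K_O2 = K_O2, K_NO3 = K_NO3),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters (%s): K = %.2f, Ks = %.2f, eta = %.2f\n",
              x$zone, x$K, x$Ks, x$eta))
  invisible(x)
}

#' Reactor state for the kinetic rate law
#'
#' @param S DMP concentration (ug L^-1, >= 0).
#' @param X_H Heterotrophic biomass, approximated by MLSS (mg L^-1, > 0
#'   for a defined specific rate).
#' @param S_O2 Dissolved oxygen (mg L^-1).
#' @param S_NO3 Nitrate (mg L^-1).
#' @param S_s Readily biodegradable substrate (mg L^-1; informational).
#' @return A list of class `kinetic_state`.
#' @export
kinetic_state <- function(S, X_H, S_O2 = 0, S_NO3 = 0, S_s = NA_real_) {
  if (any(c(S, X_H, S_O2, S_NO3) < 0, na.rm = TRUE)) {
    fwnn_stop("concentrations must be non-negative", "fwnndmp_invalid_input")
  }
  structure(list(S = S, X_H = X_H, S_O2 = S_O2, S_NO3 = S_NO3, S_s = S_s),
            class = "kinetic_state")
}

#' Zone hydrolysis rate of DMP removal
#'
#' Monod-type biomass-specific hydrolysis:
#' \deqn{r = \eta \, K \, \frac{u}{K_s + u} \, X_H, \quad u = S / X_H,}
#' optionally multiplied by the ASM2 redox switching functions for the
#' zone: aerobic \eqn{S_{O2}/(K_{O2}+S_{O2})}; anoxic
#' \eqn{K_{O2}/(K_{O2}+S_{O2}) \cdot S_{NO3}/(K_{NO3}+S_{NO3})}; anaerobic
#' \eqn{K_{O2}/(K_{O2}+S_{O2}) \cdot K_{NO3}/(K_{NO3}+S_{NO3})}. With
#' `switching = FALSE` the pure Monod law (the simplified rate used for
#' parameter fitting) is returned.
#'
#' @param state A [kinetic_state()].
#' @param params A [kinetic_params()].
#' @param switching Apply the zone's redox switching multiplier?
#' @param substrate_variable `"ratio"` uses `u = S / X_H` (ASM2 convention);
#'   `"concentration"` uses `u = S` directly.
#' @return Rate of DMP removal (ug L^-1 per internal time unit).
#' @export
hydrolysis_rate <- function(state, params, switching = TRUE,
                            substrate_variable = c("ratio", "concentration")) {
  substrate_variable <- match.arg(substrate_variable)
  if (state$X_H == 0) {
    fwnn_stop("X_H = 0: specific hydrolysis rate undefined",
              "fwnndmp_invalid_input")
  }
  u <- if (substrate_variable == "ratio") state$S / state$X_H else state$S
  r <- params$eta * params$K * u / (params$Ks + u) * state$X_H
  if (switching) r <- r * switching_multiplier(state, params)
  r
}

#' Redox switching multiplier for a zone
#'
#' @inheritParams hydrolysis_rate
#' @return Dimensionless multiplier in `(0, 1)`.
#' @export
switching_multiplier <- function(state, params) {
  o2_on <- state$S_O2 / (params$K_O2 + state$S_O2)
  o2_off <- params$K_O2 / (params$K_O2 + state$S_O2)
  no3_on <- state$S_NO3 / (params$K_NO3 + state$S_NO3)
  no3_off <- params$K_NO3 / (params$K_NO3 + state$S_NO3)
  switch(params$zone,
    aerobic = o2_on,
    anoxic = o2_off * no3_on,
    anaerobic = o2_off * no3_off
  )
}

#' Double-reciprocal (Lineweaver-Burk) transform of rate observations
#'
#' Transforms `(u, v)` pairs — substrate-to-biomass ratio and specific
#' rate — into `(x, y) = (1/u, 1/v)`. Under an exact Monod law
#' \eqn{v = K u / (K_s + u)} the transformed points fall exactly on the
#' line \eqn{y = (K_s/K)\,x + 1/K}. Non-positive observations are dropped
#' with a message.
#'
#' @param u Substrate-to-biomass ratios (> 0).
#' @param v Specific rates (> 0).
#' @return Data frame with columns `x`, `y`.
#' @export
linearize_rates <- function(u, v) {
  if (length(u) != length(v)) {
    fwnn_stop("u and v must have equal length", "fwnndmp_schema_error")
  }
  keep <- u > 0 & v > 0
  if (any(!keep)) {
    message(sprintf("linearize_rates: dropped %d non-positive observation(s)",
                    sum(!keep)))
  }
  data.frame(x = 1 / u[keep], y = 1 / v[keep])
}

#' Ordinary least squares fit of transformed rate points
#'
#' @param points Data frame with columns `x`, `y` (>= 2 distinct x values).
#' @return A list of class `linear_fit` with `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_linear <- function(points) {
  if (nrow(points) < 2 || length(unique(points$x)) < 2) {
    fwnn_stop("need at least 2 distinct x values for a linear fit",
              "fwnndmp_degenerate_design")
  }
  fit <- stats::lm(y ~ x, data = points)
  res <- stats::residuals(fit)
  sstot <- sum((points$y - mean(points$y))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(res^2) / sstot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "linear_fit")
}

#' Kinetic constants from a double-reciprocal fit
#'
#' Maps the fitted line back to Monod constants: `K = 1/intercept`,
#' `Ks = slope/intercept`. When an aerobic reference rate is supplied the
#' zone's hydrolysis reduction factor is `eta = K / K_aerobic` (capped at
#' 1); otherwise `eta = 1`.
#'
#' @param fit A `linear_fit` (intercept must be positive).
#' @param zone Zone label for the resulting [kinetic_params()].
#' @param K_aerobic Optional aerobic-zone maximum rate for computing `eta`.
#' @param K_O2,K_NO3 Switching coefficients passed through.
#' @return A [kinetic_params()] object (full precision; round to 2 decimals
#'   for reporting).
#' @export
coefficients_to_params <- function(fit, zone = "aerobic", K_aerobic = NULL,
                                   K_O2 = 0.2, K_NO3 = 0.2) {
  if (fit$intercept <= 0) {
    fwnn_stop("non-physical fit: intercept must be positive (1/K)",
              "fwnndmp_nonphysical_fit")
  }
  K <- 1 / fit$intercept
  Ks <- fit$slope / fit$intercept
  eta <- if (is.null(K_aerobic)) 1 else reduction_factor(K, K_aerobic)
  kinetic_params(zone = zone, K = K, Ks = Ks, eta = eta,
                 K_O2 = K_O2, K_NO3 = K_NO3)
}

#' Hydrolysis reduction factor from zone rate constants
#'
#' `eta = K_zone / K_aerobic`, capped at 1 (the aerobic zone is the
#' reference with `eta = 1`).
#'
#' @param K_zone,K_aerobic Positive maximum rates.
#' @return Reduction factor in `(0, 1]`.
#' @export
reduction_factor <- function(K_zone, K_aerobic) {
  if (K_aerobic <= 0 || K_zone <= 0) {
    fwnn_stop("rate constants must be positive", "fwnndmp_invalid_parameter")
  }
  min(1, K_zone / K_aerobic)
}

#' Steady-state effluent DMP through a chain of completely mixed zones
#'
#' Each zone is a completely mixed reactor at steady state:
#' \eqn{S_{in} - S_{out} = r(S_{out}) \cdot HRT}. The root is bracketed in
#' `[0, S_in]` (the removal rate is monotone in S) and solved to 1e-9.
#' Zones are chained in the given order, anaerobic to anoxic to aerobic for
#' the A/A/O train.
#'
#' @param influent_S Influent DMP (ug L^-1, >= 0).
#' @param zones List of zone descriptors, each a list with elements
#'   `params` ([kinetic_params()]), `hrt` (> 0, internal time units), and
#'   optionally `S_O2`, `S_NO3` (redox state for the switching functions).
#' @param X_H Biomass concentration (MLSS, mg L^-1).
#' @param switching Apply redox switching multipliers (`FALSE` gives the
#'   pure-Monod simplified chain).
#' @return Effluent DMP in `[0, influent_S]`.
#' @export
predict_effluent <- function(influent_S, zones, X_H, switching = TRUE) {
  if (influent_S < 0) {
    fwnn_stop("influent must be non-negative", "fwnndmp_invalid_input")
  }
  s <- influent_S
  for (zn in zones) {
    if (is.null(zn$hrt) || zn$hrt <= 0) {
      fwnn_stop("each zone needs a positive hrt", "fwnndmp_config_error")
    }
    s <- solve_zone(s, zn$params, zn$hrt, X_H,
                    S_O2 = if (is.null(zn$S_O2)) 0 else zn$S_O2,
                    S_NO3 = if (is.null(zn$S_NO3)) 0 else zn$S_NO3,
                    switching = switching)
  }
  s
}

solve_zone <- function(s_in, params, hrt, X_H, S_O2, S_NO3, switching) {
  if (s_in <= 0) return(0)
  f <- function(s_out) {
    st <- kinetic_state(S = s_out, X_H = X_H, S_O2 = S_O2, S_NO3 = S_NO3)
    s_in - s_out - hydrolysis_rate(st, params, switching = switching) * hrt
  }
  if (f(s_in) >= 0) return(s_in)  # no net removal (e.g. rate ~ 0)
  stats::uniroot(f, lower = 0, upper = s_in, tol = 1e-9)$root
}

#' Reference A/A/O kinetic calibration
#'
#' Loads the packaged per-zone calibration (double-reciprocal fit
#' coefficients and the derived K, Ks, eta for the anaerobic, anoxic and
#' aerobic zones).
#'
#' @return Data frame with columns `zone`, `slope`, `intercept`,
#'   `r_squared`, `Ks`, `K`, `eta`.
#' @export
reference_kinetics <- function() {
  jsonlite::fromJSON(system.file("extdata", "reference_kinetics.json",
                                 package = "fwnndmp", mustWork = TRUE))
}

#' Default A/A/O zone chain
#'
#' Builds the three-zone descriptor list used by [predict_effluent()] and
#' the synthetic generator, from the packaged reference calibration: the
#' aerobic maximum rate with per-zone reduction factors and half-saturation
#' constants. Zone hydraulic retention times default to (5, 5, 20) internal
#' time units, proportional to the pilot train's 40/40/160 L zone volumes.
#'
#' @param hrt Numeric length-3 vector of zone HRTs
#'   (anaerobic, anoxic, aerobic).
#' @param aerobic_S_O2 Dissolved oxygen driving the aerobic switching
#'   function (mg L^-1).
#' @param anaerobic_state,anoxic_state Fixed redox states `(S_O2, S_NO3)`
#'   for the two unaerated zones.
#' @return List of three zone descriptors (anaerobic, anoxic, aerobic).
#' @export
aao_zone_chain <- function(hrt = c(5, 5, 20), aerobic_S_O2 = 4.13,
                           anaerobic_state = c(S_O2 = 0.15, S_NO3 = 0.5),
                           anoxic_state = c(S_O2 = 0.30, S_NO3 = 2.0)) {
  ref <- reference_kinetics()
  K_aer <- ref$K[ref$zone == "aerobic"]
  row <- function(z) ref[ref$zone == z, ]
  list(
    list(params = kinetic_params("anaerobic", K = K_aer,
                                 Ks = row("anaerobic")$Ks,
                                 eta = row("anaerobic")$eta),
         hrt = hrt[1], S_O2 = unname(anaerobic_state["S_O2"]),
         S_NO3 = unname(anaerobic_state["S_NO3"])),
    list(params = kinetic_params("anoxic", K = K_aer,
                                 Ks = row("anoxic")$Ks,
                                 eta = row("anoxic")$eta),
         hrt = hrt[2], S_O2 = unname(anoxic_state["S_O2"]),
         S_NO3 = unname(anoxic_state["S_NO3"])),
    list(params = kinetic_params("aerobic", K = K_aer,
                                 Ks = row("aerobic")$Ks, eta = 1),
         hrt = hrt[3], S_O2 = aerobic_S_O2, S_NO3 = 0)
  )
}

#' Simulate noiseless Monod rate observations and recover the constants
#'
#' Convenience round-trip used for validation: generate specific rates from
#' a Monod law at the given `u` grid, optionally perturb them with
#' multiplicative noise, then linearize, fit, and extract `(K, Ks)`.
#'
#' @param K,Ks True Monod constants.
#' @param u Grid of substrate-to-biomass ratios.
#' @param noise_sd Multiplicative lognormal noise sd on the rates (0 for
#'   exact recovery).
#' @return A [kinetic_params()] with the recovered constants (zone
#'   `"aerobic"`, `eta = 1`).
#' @export
recover_monod_params <- function(K, Ks, u = seq(10, 400, length.out = 25),
                                 noise_sd = 0) {
  v <- K * u / (Ks + u)
  if (noise_sd > 0) v <- v * stats::rlnorm(length(v), 0, noise_sd)
  coefficients_to_params(fit_linear(linearize_rates(u, v)))
}
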