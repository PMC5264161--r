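#' Synthetic A/A/O dataset generator configuration
#'
#' The generator emulates the pilot study's operating envelope: influent
#' DMP at the five feed levels 30, 40, 50, 60, 80 ug L^-1 (with a small
#' uniform jitter), aerobic-zone DO uniform on [2.54, 5.72] mg L^-1, MLSS
#' around 3000 mg L^-1, and plausible activated-sludge conventions for pH
#' (uniform [6.8, 7.8]) and ORP (uniform [-250, 150] mV), neither of which
#' is reported for the plant. Effluent DMP is produced either by the
#' three-zone kinetic chain (`teacher = "kinetic"`, with multiplicative
#' lognormal noise) or by a teacher FWNN on scaled inputs
#' (`teacher = "fwnn"`, with additive Gaussian noise).
#'
#' In kinetic mode pH and ORP do not enter the effluent mechanism — they
#' are nuisance inputs, which deliberately tests that data-driven models
#' tolerate uninformative variables.
#'
#' @param n_samples Number of rows (the study's campaign had 50).
#' @param seed RNG seed.
#' @param noise_sd Lognormal sdlog of the multiplicative effluent noise
#'   (kinetic mode) or additive sd in scaled units (fwnn mode).
#' @param dmp_levels Influent DMP feed levels (ug L^-1).
#' @param dmp_jitter Half-width of the uniform jitter around each level.
#' @param do_range Aerobic DO range (mg L^-1).
#' @param mlss_mean,mlss_sd MLSS normal distribution (mg L^-1).
#' @param ph_range,orp_range Nuisance input ranges.
#' @param hrt Zone hydraulic retention times (anaerobic, anoxic, aerobic),
#'   internal time units.
#' @param zones Optional zone chain overriding [aao_zone_chain()] defaults.
#' @param switching Drive the kinetic teacher with the redox switching
#'   functions (the aerobic multiplier uses each sample's DO column).
#' @param teacher `"kinetic"` or `"fwnn"`.
#' @param teacher_fwnn An `fwnn_params` teacher (fwnn mode); defaults to
#'   [make_teacher_fwnn()] with 8 rules and 5 inputs.
#' @param fwnn_output_range Concentration range the fwnn teacher's scaled
#'   output is mapped onto (ug L^-1).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 50, seed = NULL, noise_sd = 0.05,
                             dmp_levels = c(30, 40, 50, 60, 80),
                             dmp_jitter = 2,
                             do_range = c(2.54, 5.72),
                             mlss_mean = 3000, mlss_sd = 150,
                             ph_range = c(6.8, 7.8),
                             orp_range = c(-250, 150),
                             hrt = c(5, 5, 20),
                             zones = NULL,
                             switching = TRUE,
                             teacher = c("kinetic", "fwnn"),
                             teacher_fwnn = NULL,
                             fwnn_output_range = c(0.5, 25)) {
  teacher <- match.arg(teacher)
  if (n_samples < 1) {
    fwnn_stop("n_samples must be at least 1", "fwnndmp_config_error")
  }
  if (noise_sd < 0) {
    fwnn_stop("noise_sd must be non-negative", "fwnndmp_config_error")
  }
  if (do_range[2] <= do_range[1] || ph_range[2] <= ph_range[1] ||
      orp_range[2] <= orp_range[1] || any(hrt <= 0)) {
    fwnn_stop("degenerate range in generator config", "fwnndmp_config_error")
  }
  structure(
    list(n_samples = n_samples, seed = seed, noise_sd = noise_sd,
         dmp_levels = dmp_levels, dmp_jitter = dmp_jitter,
         do_range = do_range, mlss_mean = mlss_mean, mlss_sd = mlss_sd,
         ph_range = ph_range, orp_range = orp_range, hrt = hrt,
         zones = zones, switching = switching, teacher = teacher,
         teacher_fwnn = teacher_fwnn, fwnn_output_range = fwnn_output_range),
    class = "generator_config"
  )
}

#' Generate a synthetic A/A/O process dataset
#'
#' Draws the five input columns within the configured operating envelope
#' and produces effluent DMP from the configured teacher (see
#' [generator_config()]). Fully reproducible under a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A `process_dataset` with provenance `"synthetic"`.
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  dmp_in <- sample(config$dmp_levels, n, replace = TRUE) +
    stats::runif(n, -config$dmp_jitter, config$dmp_jitter)
  dmp_in <- pmax(dmp_in, 0)
  do <- stats::runif(n, config$do_range[1], config$do_range[2])
  mlss <- pmax(stats::rnorm(n, config$mlss_mean, config$mlss_sd), 1)
  ph <- stats::runif(n, config$ph_range[1], config$ph_range[2])
  orp <- stats::runif(n, config$orp_range[1], config$orp_range[2])

  if (config$teacher == "kinetic") {
    base_zones <- if (is.null(config$zones)) {
      aao_zone_chain(hrt = config$hrt)
    } else {
      config$zones
    }
    eff <- vapply(seq_len(n), function(i) {
      zones <- base_zones
      zones[[length(zones)]]$S_O2 <- do[i]
      predict_effluent(dmp_in[i], zones, X_H = mlss[i],
                       switching = config$switching)
    }, numeric(1))
    if (config$noise_sd > 0) {
      eff <- eff * stats::rlnorm(n, 0, config$noise_sd)
    }
    eff <- pmin(eff, dmp_in)  # noise cannot create DMP
  } else {
    teacher <- config$teacher_fwnn
    if (is.null(teacher)) teacher <- make_teacher_fwnn(8, 5, seed = 1)
    xs <- cbind(
      scale_range(ph, config$ph_range),
      scale_range(dmp_in, range(config$dmp_levels) +
                    c(-config$dmp_jitter, config$dmp_jitter)),
      scale_range(do, config$do_range),
      scale_range(orp, config$orp_range),
      scale_range(mlss, config$mlss_mean + c(-4, 4) * config$mlss_sd)
    )
    z <- fwnn_predict(teacher, xs)
    if (config$noise_sd > 0) z <- z + stats::rnorm(n, 0, config$noise_sd)
    r <- config$fwnn_output_range
    eff <- pmax(r[1] + (pmin(pmax(z, -1), 1) + 1) / 2 * (r[2] - r[1]), 0)
  }

  process_dataset(
    data.frame(pH = ph, DMP_in = dmp_in, DO = do, ORP = orp,
               MLSS = mlss, DMP_eff = eff),
    provenance = "synthetic"
  )
}

scale_range <- function(v, r) 2 * (v - r[1]) / (r[2] - r[1]) - 1

#' Random well-conditioned teacher FWNN
#'
#' Draws a teacher network for function-recovery experiments: centers and
#' translations uniform in [-1, 1], spread and dilation magnitudes in
#' [0.5, 2], weights in [-2, 2]. Deterministic per seed; outputs are finite
#' and smooth on the scaled input cube.
#'
#' @param n_rules,n_inputs Architecture.
#' @param seed RNG seed.
#' @param aggregation,wavelet Forward settings.
#' @return An `fwnn_params` object.
#' @export
make_teacher_fwnn <- function(n_rules, n_inputs, seed = 1,
                              aggregation = "normalized",
                              wavelet = "mexhat") {
  if (n_rules < 1) fwnn_stop("n_rules must be >= 1", "fwnndmp_config_error")
  if (!is.null(seed)) set.seed(seed)
  k <- n_rules * n_inputs
  fwnn_params(
    centers = matrix(stats::runif(k, -1, 1), n_rules, n_inputs),
    spreads = matrix(stats::runif(k, 0.5, 2), n_rules, n_inputs),
    dilations = matrix(stats::runif(k, 0.5, 2), n_rules, n_inputs),
    translations = matrix(stats::runif(k, -1, 1), n_rules, n_inputs),
    weights = stats::runif(n_rules, -2, 2),
    aggregation = aggregation, wavelet = wavelet
  )
}

#' Generate teacher-student benchmark data
#'
#' Samples scaled inputs uniformly on `[-1, 1]^p` and labels them with a
#' teacher FWNN's forward pass, optionally plus additive Gaussian noise.
#' This is the function-recovery benchmark used to validate the hybrid
#' training scheme.
#'
#' @param teacher An `fwnn_params` teacher network.
#' @param n Number of samples.
#' @param noise_sd Additive Gaussian noise sd (scaled units).
#' @param seed RNG seed.
#' @return List with `x` (matrix `n x p`) and `y`.
#' @export
generate_teacher_data <- function(teacher, n, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- teacher$n_inputs
  x <- matrix(stats::runif(n * p, -1, 1), n, p)
  y <- fwnn_predict(teacher, x)
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

#' Write generator provenance sidecar
#'
#' Records the full generator configuration and seed alongside a written
#' dataset, so every synthetic file is reproducible.
#'
#' @param config The [generator_config()] used.
#' @param path Output JSON path.
#' @export
write_generator_provenance <- function(config, path) {
  out <- unclass(config)
  out$teacher_fwnn <- if (!is.null(config$teacher_fwnn)) "embedded" else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
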