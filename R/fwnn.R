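#' @keywords internal
"_PACKAGE"

# condition helper: all package errors carry class "fwnndmp_error" plus a
# specific subclass so callers (e.g. the GA fitness wrapper) can catch them.
fwnn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fwnndmp_error", "error")))
}

#' Construct a fuzzy wavelet neural network parameter set
#'
#' Bundles every trainable quantity of the five-layer fuzzy wavelet network:
#' Gaussian antecedent centers and spreads (one per rule and input), wavelet
#' dilation and translation parameters for the consequent wavelons, and one
#' consequent weight per rule. All matrices are `n_rules x n_inputs`.
#'
#' Spreads and dilations may be negative (they enter the model through even
#' functions, so sign never changes the output) but must be non-zero, since
#' both are divisors.
#'
#' @param centers Numeric matrix of Gaussian centers, `n_rules x n_inputs`,
#'   in scaled-input units.
#' @param spreads Numeric matrix of Gaussian spreads, same shape; non-zero.
#' @param dilations Numeric matrix of wavelet scale parameters; non-zero.
#' @param translations Numeric matrix of wavelet shift parameters.
#' @param weights Numeric vector of consequent weights, length `n_rules`.
#' @param input_names Optional character vector naming the inputs.
#' @param aggregation Output-layer aggregation: `"normalized"` (default;
#'   firing-strength-weighted average, the Takagi-Sugeno reading) or `"sum"`.
#' @param wavelet Mother wavelet family: `"mexhat"` (default; Mexican hat
#'   \eqn{(1-z^2)e^{-z^2/2}}) or `"morlet"` (\eqn{\cos(5z)e^{-z^2/2}}).
#'
#' @return An object of class `fwnn_params`.
#' @examples
#' p <- fwnn_params(
#'   centers = matrix(0, 2, 2), spreads = matrix(1, 2, 2),
#'   dilations = matrix(1, 2, 2), translations = matrix(0, 2, 2),
#'   weights = c(1, -1)
#' )
#' fwnn_forward(p, c(0, 0))$output
#' @export
fwnn_params <- function(centers, spreads, dilations, translations, weights,
                        input_names = NULL,
                        aggregation = c("normalized", "sum"),
                        wavelet = c("mexhat", "morlet")) {
  aggregation <- match.arg(aggregation)
  wavelet <- match.arg(wavelet)
  centers <- as.matrix(centers)
  spreads <- as.matrix(spreads)
  dilations <- as.matrix(dilations)
  translations <- as.matrix(translations)
  weights <- as.numeric(weights)
  obj <- structure(
    list(
      n_inputs = ncol(centers), n_rules = nrow(centers),
      centers = centers, spreads = spreads,
      dilations = dilations, translations = translations,
      weights = weights, input_names = input_names,
      aggregation = aggregation, wavelet = wavelet
    ),
    class = "fwnn_params"
  )
  validate_fwnn_params(obj)
  obj
}

#' Validate an `fwnn_params` object
#'
#' Checks shape consistency (all four matrices `n_rules x n_inputs`, weight
#' vector of length `n_rules`) and that every spread and dilation is non-zero
#' and finite. Errors name the offending rule and input index.
#'
#' @param params An `fwnn_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_fwnn_params <- function(params) {
  dims <- c(params$n_rules, params$n_inputs)
  for (nm in c("centers", "spreads", "dilations", "translations")) {
    m <- params[[nm]]
    if (!is.matrix(m) || !all(dim(m) == dims)) {
      fwnn_stop(sprintf("'%s' must be a %d x %d matrix", nm, dims[1], dims[2]),
                "fwnndmp_invalid_parameter")
    }
    if (any(!is.finite(m))) {
      fwnn_stop(sprintf("'%s' contains non-finite values", nm),
                "fwnndmp_invalid_parameter")
    }
  }
  if (length(params$weights) != params$n_rules) {
    fwnn_stop("'weights' must have one entry per rule",
              "fwnndmp_invalid_parameter")
  }
  for (nm in c("spreads", "dilations")) {
    bad <- which(params[[nm]] == 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      fwnn_stop(
        sprintf("zero %s at rule %d, input %d (enters as a divisor)",
                sub("s$", "", nm), bad[1, 1], bad[1, 2]),
        "fwnndmp_invalid_parameter"
      )
    }
  }
  if (!is.null(params$input_names) &&
      length(params$input_names) != params$n_inputs) {
    fwnn_stop("'input_names' length must equal n_inputs",
              "fwnndmp_invalid_parameter")
  }
  invisible(params)
}

#' @export
print.fwnn_params <- function(x, ...) {
  cat(sprintf(
    "Fuzzy wavelet neural network parameters\n  rules: %d, inputs: %d (%s)\n  wavelet: %s, aggregation: %s\n",
    x$n_rules, x$n_inputs,
    if (is.null(x$input_names)) "unnamed" else paste(x$input_names, collapse = ", "),
    x$wavelet, x$aggregation
  ))
  cat(sprintf("  weight range: [%.4g, %.4g]\n",
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Read / write FWNN parameters as JSON
#'
#' The on-disk format stores `n_inputs`, `n_rules`, `input_names`, the four
#' parameter matrices (row per rule), the weight vector, and the
#' `aggregation` and `wavelet` settings.
#'
#' @param path File path.
#' @return `read_fwnn_params` returns an `fwnn_params` object;
#'   `write_fwnn_params` returns `path` invisibly.
#' @export
read_fwnn_params <- function(path) {
  if (!file.exists(path)) {
    fwnn_stop(sprintf("parameter file not found: %s", path), "fwnndmp_io_error")
  }
  raw <- jsonlite::fromJSON(path)
  fwnn_params(
    centers = raw$centers, spreads = raw$spreads,
    dilations = raw$dilations, translations = raw$translations,
    weights = raw$weights,
    input_names = raw$input_names,
    aggregation = if (is.null(raw$aggregation)) "normalized" else raw$aggregation,
    wavelet = if (is.null(raw$wavelet)) "mexhat" else raw$wavelet
  )
}

#' @rdname read_fwnn_params
#' @param params An `fwnn_params` object to serialize.
#' @export
write_fwnn_params <- function(params, path) {
  validate_fwnn_params(params)
  out <- list(
    n_inputs = params$n_inputs, n_rules = params$n_rules,
    input_names = params$input_names,
    centers = params$centers, spreads = params$spreads,
    dilations = params$dilations, translations = params$translations,
    weights = params$weights,
    aggregation = params$aggregation, wavelet = params$wavelet
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Packaged reference FWNN calibration
#'
#' Loads the reference parameter set shipped with the package: an 8-rule,
#' 5-input network for the A/A/O DMP process with input order
#' pH, DMP_in, DO, ORP, MLSS.
#'
#' @return An `fwnn_params` object.
#' @export
reference_fwnn_params <- function() {
  read_fwnn_params(system.file("extdata", "reference_fwnn.json",
                               package = "fwnndmp", mustWork = TRUE))
}
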