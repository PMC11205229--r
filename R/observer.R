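#' Simulated observer parameters
#'
#' A frequency-of-seeing (psychometric) observer: responses are drawn
#' from a Gaussian psychometric function whose slope (SD) grows as
#' sensitivity falls, following the Henson-type relation
#' `sd = min(cap, exp(A * sensitivity + B))`, mixed with false-positive
#' and false-negative response rates.
#'
#' @param fp False-positive rate (probability of "seen" for an
#'   unseeable stimulus).
#' @param fn False-negative rate (probability of "not seen" for a
#'   clearly visible stimulus).
#' @param slope_A Henson coefficient, per dB (default -0.081).
#' @param slope_B Henson intercept (default 3.27).
#' @param slope_cap Maximum psychometric SD, dB (default 6).
#' @return An `observer_params` object.
#' @export
observer_params <- function(fp = 0.05, fn = 0.05, slope_A = -0.081,
                            slope_B = 3.27, slope_cap = 6) {
  stopifnot(fp >= 0, fn >= 0, fp + fn < 1, slope_cap > 0)
  structure(list(fp = fp, fn = fn, slope_A = slope_A, slope_B = slope_B,
                 slope_cap = slope_cap),
            class = "observer_params")
}

#' Observer presets
#'
#' `reliable`: 5% false-positive and false-negative responses;
#' `unreliable`: 20% of both.
#'
#' @param name `"reliable"` or `"unreliable"`.
#' @return An [observer_params()].
#' @export
observer_preset <- function(name = c("reliable", "unreliable")) {
  name <- match.arg(name)
  if (name == "reliable") observer_params(fp = 0.05, fn = 0.05)
  else observer_params(fp = 0.20, fn = 0.20)
}

#' Henson psychometric slope
#'
#' SD of the psychometric function as a function of true sensitivity:
#' `min(slope_cap, exp(slope_A * sensitivity + slope_B))`. With the
#' defaults the SD is capped at 6 dB at low sensitivities and shrinks to
#' about 1 dB at high sensitivities.
#'
#' @param sensitivity True sensitivity, dB; vectorized.
#' @param params An [observer_params()].
#' @return SD, dB.
#' @export
henson_sd <- function(sensitivity, params = observer_params()) {
  pmin(params$slope_cap, exp(params$slope_A * sensitivity + params$slope_B))
}

#' Probability of a "seen" response
#'
#' `fp + (1 - fp - fn) * Phi((true_t - stimulus) / henson_sd(true_t))`:
#' a Gaussian frequency-of-seeing curve floored at the false-positive
#' rate and ceilinged at one minus the false-negative rate.
#'
#' @param true_t True threshold, dB.
#' @param stimulus Presented intensity, dB (higher dB = dimmer).
#' @param params An [observer_params()].
#' @return Probability in `[fp, 1 - fn]`; vectorized.
#' @export
prob_seen <- function(true_t, stimulus, params = observer_params()) {
  sd <- henson_sd(true_t, params)
  params$fp + (1 - params$fp - params$fn) *
    stats::pnorm((true_t - stimulus) / sd)
}

#' Draw a response from the simulated observer
#'
#' Bernoulli draw from [prob_seen()] using the current R random stream;
#' seed the stream (e.g. `set.seed()`) for reproducibility.
#'
#' @inheritParams prob_seen
#' @return Logical: `TRUE` for "seen".
#' @export
respond <- function(true_t, stimulus, params = observer_params()) {
  stats::runif(length(true_t)) < prob_seen(true_t, stimulus, params)
}

#' One synthetic eye
#'
#' Ground truth for a simulated examination: per-location true
#' sensitivities, the consistent GCL thickness map, fovea/ONH geometry,
#' and cohort labels.
#'
#' @param true_thresholds 68 sensitivities, dB in `[0, 40]`.
#' @param gcl_map A [thickness_map()] or `NULL`.
#' @param cohort `"healthy"` or `"glaucoma"`.
#' @param severity `"none"`, `"early"`, `"moderate"` or `"advanced"`;
#'   healthy eyes must be `"none"`.
#' @param fovea,onh_center Fundus-reference positions, degrees.
#' @param id Optional eye identifier.
#' @return An `eye_profile` object.
#' @export
eye_profile <- function(true_thresholds, gcl_map = NULL,
                        cohort = c("healthy", "glaucoma"),
                        severity = c("none", "early", "moderate", "advanced"),
                        fovea = c(0, 0), onh_center = c(15, 2), id = NULL) {
  cohort <- match.arg(cohort)
  severity <- match.arg(severity)
  stopifnot(length(true_thresholds) == 68,
            all(true_thresholds >= 0), all(true_thresholds <= 40))
  if (cohort == "healthy" && severity != "none") {
    stop("healthy eyes must have severity 'none'")
  }
  if (cohort == "glaucoma" && severity == "none") {
    stop("glaucoma eyes need a severity stratum")
  }
  structure(
    list(true_thresholds = as.numeric(true_thresholds), gcl_map = gcl_map,
         cohort = cohort, severity = severity,
         fovea = c(x = fovea[[1]], y = fovea[[2]]),
         onh_center = c(x = onh_center[[1]], y = onh_center[[2]]),
         id = id),
    class = "eye_profile"
  )
}

#' @export
print.eye_profile <- function(x, ...) {
  cat(sprintf("synthetic eye%s: %s (%s), mean sensitivity %.1f dB%s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$cohort, x$severity, mean(x$true_thresholds),
              if (is.null(x$gcl_map)) ", no GCL map" else ""))
  invisible(x)
}
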