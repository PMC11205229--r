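#' Candidate-threshold domain
#'
#' The discrete support of every prior/posterior: candidate thresholds
#' from `min` to `max` dB in uniform `step` increments (default 0-40 dB
#' in 1-dB steps, 41 bins).
#'
#' @param min,max Domain endpoints, dB.
#' @param step Uniform spacing, dB.
#' @return Ascending numeric vector.
#' @export
zest_domain <- function(min = 0, max = 40, step = 1) {
  stopifnot(step > 0, max > min)
  seq(min, max, by = step)
}

#' Discrete probability distribution over candidate thresholds
#'
#' @param domain Ascending, uniformly spaced candidate thresholds (dB).
#' @param mass Nonnegative weights, one per candidate; normalized to sum 1.
#' @return A `discrete_pdf`: list with `domain` and `mass`.
#' @export
discrete_pdf <- function(domain, mass) {
  stopifnot(length(domain) == length(mass), length(domain) >= 1)
  if (any(mass < 0) || anyNA(mass)) stop("mass must be nonnegative and finite")
  if (length(domain) > 1) {
    dd <- diff(domain)
    if (any(dd <= 0) || diff(range(dd)) > 1e-9 * dd[1]) {
      stop("domain must be ascending with uniform spacing")
    }
  }
  s <- sum(mass)
  if (s <= 0) stop("total mass must be positive")
  structure(list(domain = as.numeric(domain), mass = as.numeric(mass) / s),
            class = "discrete_pdf")
}

#' @export
print.discrete_pdf <- function(x, ...) {
  cat(sprintf("discrete pdf over [%g, %g] dB (%d bins): mean %.2f, sd %.2f\n",
              min(x$domain), max(x$domain), length(x$domain),
              pdf_mean(x), pdf_sd(x)))
  invisible(x)
}

check_pdf <- function(p) {
  if (!inherits(p, "discrete_pdf")) stop("expected a discrete_pdf")
  if (abs(sum(p$mass) - 1) > 1e-6) stop("pdf is not normalized")
  invisible(p)
}

#' Prior mixture configuration
#'
#' Shapes of the normal and abnormal prior components and their default
#' mixing. The defaults give the standard 4:1 normal:abnormal mixture
#' (`abnormal_weight = 0.2`) with Gaussian bumps standing in for
#' population threshold histograms, plus a small uniform floor that
#' keeps every bin reachable after repeated likelihood updates.
#'
#' @param normal_sd SD of the normal component, dB.
#' @param abnormal_peak Mode of the abnormal component, dB.
#' @param abnormal_sd SD of the abnormal component, dB.
#' @param abnormal_weight Abnormal mixing fraction in `[0, 1]`.
#' @param floor Uniform floor fraction in `[0, 0.05]`.
#' @return A `prior_config` list.
#' @export
prior_config <- function(normal_sd = 5, abnormal_peak = 3, abnormal_sd = 4,
                         abnormal_weight = 0.2, floor = 0.001) {
  stopifnot(normal_sd > 0, abnormal_sd > 0,
            abnormal_weight >= 0, abnormal_weight <= 1,
            floor >= 0, floor <= 0.05)
  structure(list(normal_sd = normal_sd, abnormal_peak = abnormal_peak,
                 abnormal_sd = abnormal_sd, abnormal_weight = abnormal_weight,
                 floor = floor),
            class = "prior_config")
}

#' Discretized Gaussian component
#'
#' A Gaussian bump evaluated at the domain points and renormalized; the
#' mode of the mass sits at the domain point nearest `peak`.
#'
#' @param peak Component mode, dB.
#' @param sd Component SD, dB (> 0).
#' @param domain From [zest_domain()].
#' @return A [discrete_pdf()].
#' @export
make_component <- function(peak, sd, domain = zest_domain()) {
  if (!is.finite(peak)) stop("peak must be finite")
  if (sd <= 0) stop("sd must be positive")
  discrete_pdf(domain, stats::dnorm(domain, mean = peak, sd = sd))
}

# shared mixture construction for both strategies
make_mixture_prior <- function(normal_peak, abnormal_weight, cfg, domain) {
  normal <- make_component(normal_peak, cfg$normal_sd, domain)
  abnormal <- make_component(cfg$abnormal_peak, cfg$abnormal_sd, domain)
  mix <- (1 - abnormal_weight) * normal$mass + abnormal_weight * abnormal$mass
  n <- length(domain)
  discrete_pdf(domain, (1 - cfg$floor) * mix + cfg$floor / n)
}

#' Standard ZEST prior
#'
#' Mixture of a normal-threshold component peaked at the normative
#' sensitivity and an abnormal component peaked near 0 dB, in the
#' configured proportion (default 4:1), with a uniform floor.
#'
#' @param normative Normative sensitivity at the location, dB in `[0, 40]`.
#' @param cfg A [prior_config()].
#' @param domain From [zest_domain()].
#' @return A [discrete_pdf()].
#' @export
make_standard_prior <- function(normative, cfg = prior_config(),
                                domain = zest_domain()) {
  stopifnot(normative >= min(domain), normative <= max(domain))
  make_mixture_prior(normative, cfg$abnormal_weight, cfg, domain)
}

#' Structurally individualized (S-ZEST) prior
#'
#' Same construction as [make_standard_prior()], but the normal
#' component is centered on the sensitivity predicted by the
#' structure-function model and the abnormal mixing fraction is supplied
#' per location (from [predict_abnormal_weight()]).
#'
#' @param predicted Predicted sensitivity, dB in `[0, 40]`.
#' @param abnormal_weight Mixing fraction in `[0, 1]`.
#' @param cfg A [prior_config()].
#' @param domain From [zest_domain()].
#' @return A [discrete_pdf()].
#' @export
make_structural_prior <- function(predicted, abnormal_weight,
                                  cfg = prior_config(),
                                  domain = zest_domain()) {
  stopifnot(predicted >= min(domain), predicted <= max(domain),
            abnormal_weight >= 0, abnormal_weight <= 1)
  make_mixture_prior(predicted, abnormal_weight, cfg, domain)
}

#' Moments of a discrete pdf
#'
#' Probability-weighted mean and standard deviation over the domain.
#'
#' @param p A [discrete_pdf()].
#' @return dB.
#' @export
pdf_mean <- function(p) {
  check_pdf(p)
  sum(p$domain * p$mass)
}

#' @rdname pdf_mean
#' @export
pdf_sd <- function(p) {
  check_pdf(p)
  m <- sum(p$domain * p$mass)
  sqrt(max(0, sum(p$domain^2 * p$mass) - m^2))
}

#' Pdf text I/O
#'
#' Two-column delimited text (`domain`, `mass`).
#'
#' @param p A [discrete_pdf()].
#' @param path File path.
#' @name pdf_io
#' @export
write_pdf <- function(p, path) {
  utils::write.csv(data.frame(domain = p$domain, mass = p$mass), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname pdf_io
#' @export
read_pdf <- function(path) {
  d <- utils::read.csv(path)
  discrete_pdf(d$domain, d$mass)
}
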