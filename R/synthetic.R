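#' Normative sensitivity map ("hill of vision" stand-in)
#'
#' Per-location normative sensitivity declining linearly with
#' eccentricity: `S = foveal_db - slope_db_per_deg * ecc`. The defaults
#' (31 dB foveal, 0.35 dB/deg) give a mean 10-2 sensitivity of about
#' 28.9 dB, the healthy cohort mean the synthetic world emulates.
#'
#' @param grid A `vf_grid`; nominal eccentricities are used (rotation
#'   does not change eccentricity).
#' @param foveal_db Foveal sensitivity, dB in `[25, 40]`.
#' @param slope_db_per_deg Decline, dB per degree.
#' @return Numeric vector of 68 normative sensitivities, dB.
#' @export
make_normative_map <- function(grid, foveal_db = 31, slope_db_per_deg = 0.35) {
  stopifnot(inherits(grid, "vf_grid"), foveal_db >= 25, foveal_db <= 40)
  ecc <- sqrt(grid$x_nominal^2 + grid$y_nominal^2)
  foveal_db - slope_db_per_deg * ecc
}

# continuous version of the normative surface, used to build rasters
normative_field <- function(foveal_db = 31, slope_db_per_deg = 0.35) {
  force(foveal_db); force(slope_db_per_deg)
  function(x, y) foveal_db - slope_db_per_deg * sqrt(x^2 + y^2)
}

# smooth hemifield defect field (dB of loss, >= 0) respecting the
# horizontal raphe; advanced eyes damage both hemifields (primary at the
# drawn depth, secondary at 0.85x) so whole-eye loss can reach the
# advanced range. Depths are calibrated once against the cohort means
# the generator emulates. Uses the current R random stream.
severity_depth_db <- c(early = 5, moderate = 12, advanced = 22)

gen_defect_field <- function(grid, severity, depth_sd = 2, bump_sigma = 4,
                             base_frac = 0.3) {
  target <- severity_depth_db[[severity]]
  depth <- max(1, stats::rnorm(1, target, depth_sd))
  sgn <- sample(c(-1, 1), 1)  # +1: superior hemifield affected
  one_hemi <- function(s, D) {
    cx <- stats::runif(1, -4, 4)
    cy <- s * stats::runif(1, 2, 6)
    g <- function(x, y) {
      base_frac + (1 - base_frac) *
        exp(-((x - cx)^2 + (y - cy)^2) / (2 * bump_sigma^2))
    }
    in_hemi <- sign(grid$y_nominal) == s
    scale <- D / mean(g(grid$x_nominal[in_hemi], grid$y_nominal[in_hemi]))
    list(s = s, scale = scale, g = g)
  }
  hemis <- list(one_hemi(sgn, depth))
  if (severity == "advanced") hemis <- c(hemis, list(one_hemi(-sgn, 0.85 * depth)))
  f <- function(x, y) {
    d <- numeric(length(x))
    for (h in hemis) {
      m <- sign(y) == h$s
      d[m] <- d[m] + h$scale * h$g(x[m], y[m])
    }
    d
  }
  attr(f, "depth") <- depth
  attr(f, "sign") <- sgn
  f
}

# invert r -> r + d(r) by table lookup (the mapping is strictly
# increasing for the default model parameters)
inverse_displacement <- function(model, max_r = 30) {
  r <- seq(0, max_r, by = 0.01)
  rp <- r + model(r)
  o <- order(rp)
  function(q) stats::approx(rp[o], r[o], xout = q, rule = 2)$y
}

# GCL raster consistent with a sensitivity surface: each pixel's retinal
# position is pulled back through the displacement model to its visual
# field position, the surface sensitivity there is inverted through the
# structure-function model, and 10% multiplicative lognormal noise is
# applied.
gen_gcl_map <- function(sens_fun, sf = sf_params(), pixel_size = 0.25,
                        half_extent = 15, thickness_noise = 0.1,
                        displacement = drasdo_displacement()) {
  ax <- seq(-half_extent, half_extent, by = pixel_size)
  inv <- inverse_displacement(displacement)
  xg <- rep(ax, each = length(ax))
  yg <- rep(rev(ax), times = length(ax))  # row 1 = superior
  rp <- sqrt(xg^2 + yg^2)
  r <- inv(rp)
  scl <- ifelse(rp > 0, r / rp, 1)
  s <- pmin(40, pmax(0, sens_fun(xg * scl, yg * scl)))
  thick <- 10^((s - sf$intercept) / sf$slope)
  if (thickness_noise > 0) {
    thick <- thick * exp(stats::rnorm(length(thick), 0, thickness_noise))
  }
  thick <- pmin(150, pmax(0.5, thick))
  thickness_map(matrix(thick, nrow = length(ax), ncol = length(ax)),
                origin = c(0, 0), pixel_size = pixel_size)
}

#' Generate a healthy synthetic eye
#'
#' True thresholds are the normative map plus a between-eye offset
#' `N(0, between_eye_sd)` and per-location noise `N(0, location_sd)`,
#' clipped to `[0, 40]` dB. The GCL thickness map is generated by
#' inverting the structure-function model on the eye's sensitivity
#' surface with multiplicative lognormal noise, so structure and
#' function are consistent by construction.
#'
#' @param grid A `vf_grid` (unrotated; the synthetic world places the
#'   ONH on the horizontal so the fovea-disc axis needs no rotation).
#' @param foveal_db,slope_db_per_deg Normative surface parameters.
#' @param between_eye_sd Between-eye offset SD, dB (default 1.5,
#'   matching the healthy cohort spread emulated).
#' @param location_sd Per-location noise SD, dB.
#' @param sf An [sf_params()] used for the thickness inversion.
#' @param thickness_noise Lognormal sdlog of thickness noise.
#' @param seed Integer seed (`NULL`: use current stream).
#' @param id Optional identifier.
#' @return An [eye_profile()] with `gcl_map`.
#' @export
gen_healthy_eye <- function(grid, foveal_db = 31, slope_db_per_deg = 0.35,
                            between_eye_sd = 1.5, location_sd = 1,
                            sf = sf_params(), thickness_noise = 0.1,
                            seed = NULL, id = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- normative_field(foveal_db, slope_db_per_deg)
  b <- stats::rnorm(1, 0, between_eye_sd)
  eps <- stats::rnorm(nrow(grid), 0, location_sd)
  truth <- pmin(40, pmax(0, nf(grid$x_nominal, grid$y_nominal) + b + eps))
  surface <- function(x, y) nf(x, y) + b
  map <- gen_gcl_map(surface, sf = sf, thickness_noise = thickness_noise)
  eye_profile(truth, gcl_map = map, cohort = "healthy", severity = "none",
              fovea = c(0, 0), onh_center = c(15, 0), id = id)
}

#' Generate a glaucomatous synthetic eye
#'
#' As [gen_healthy_eye()], minus a smooth hemifield defect field that
#' respects the horizontal raphe: one randomly signed hemifield carries
#' a spatially smooth loss whose mean depth is drawn around the severity
#' target (early ~5 dB, moderate ~12 dB, advanced ~22 dB); advanced eyes
#' additionally damage the fellow hemifield at 0.85 times the drawn
#' depth. The GCL map is generated from the same defective surface, so
#' thinning co-locates with the functional defect.
#'
#' @inheritParams gen_healthy_eye
#' @param severity `"early"`, `"moderate"` or `"advanced"`.
#' @return An [eye_profile()] with `gcl_map`.
#' @export
gen_glaucoma_eye <- function(grid, severity = c("early", "moderate", "advanced"),
                             foveal_db = 31, slope_db_per_deg = 0.35,
                             between_eye_sd = 1.5, location_sd = 1,
                             sf = sf_params(), thickness_noise = 0.1,
                             seed = NULL, id = NULL) {
  severity <- match.arg(severity)
  if (!is.null(seed)) set.seed(seed)
  nf <- normative_field(foveal_db, slope_db_per_deg)
  b <- stats::rnorm(1, 0, between_eye_sd)
  defect <- gen_defect_field(grid, severity)
  eps <- stats::rnorm(nrow(grid), 0, location_sd)
  surface <- function(x, y) nf(x, y) + b - defect(x, y)
  truth <- pmin(40, pmax(0, surface(grid$x_nominal, grid$y_nominal) + eps))
  map <- gen_gcl_map(surface, sf = sf, thickness_noise = thickness_noise)
  eye_profile(truth, gcl_map = map, cohort = "glaucoma", severity = severity,
              fovea = c(0, 0), onh_center = c(15, 0), id = id)
}

#' Cohort specification
#'
#' Defaults emulate the simulation cohort: 21 healthy and 32
#' glaucomatous eyes with a 5 early / 8 moderate / 19 advanced split.
#'
#' @param n_healthy,n_glaucoma Eye counts.
#' @param severity_mix Named fractions over early/moderate/advanced,
#'   summing to 1.
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 21, n_glaucoma = 32,
                        severity_mix = c(early = 5, moderate = 8, advanced = 19) / 32,
                        seed = 1) {
  stopifnot(n_healthy >= 0, n_glaucoma >= 0,
            abs(sum(severity_mix) - 1) < 1e-9 || n_glaucoma == 0)
  structure(list(n_healthy = n_healthy, n_glaucoma = n_glaucoma,
                 severity_mix = severity_mix, seed = seed),
            class = "cohort_spec")
}

# largest-remainder apportionment of n into the severity strata
severity_counts <- function(n, mix) {
  if (n == 0) return(stats::setNames(integer(3), c("early", "moderate", "advanced")))
  raw <- n * mix[c("early", "moderate", "advanced")]
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  stats::setNames(as.integer(k), c("early", "moderate", "advanced"))
}

#' Generate a synthetic cohort
#'
#' Reproducible from the spec's master seed: per-eye seeds are drawn
#' once from the seeded stream, so eyes are independent of generation
#' order.
#'
#' @param spec A [cohort_spec()].
#' @param grid A `vf_grid`.
#' @param ... Passed to the per-eye generators.
#' @return A `cohort`: list with `eyes` (list of [eye_profile()]) and
#'   `manifest` (data frame: `id`, `cohort`, `severity`, `seed`,
#'   `mean_truth`).
#' @export
gen_cohort <- function(spec, grid, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_healthy + spec$n_glaucoma
  sev_n <- severity_counts(spec$n_glaucoma, spec$severity_mix)
  sev <- rep(c("early", "moderate", "advanced"), times = sev_n)
  labels <- c(rep("healthy", spec$n_healthy), sev)
  eyes <- vector("list", n)
  if (n > 0) {
    set.seed(spec$seed)
    seeds <- sample.int(.Machine$integer.max - 1, n)
    for (k in seq_len(n)) {
      id <- sprintf("eye%03d", k)
      eyes[[k]] <- if (labels[k] == "healthy") {
        gen_healthy_eye(grid, seed = seeds[k], id = id, ...)
      } else {
        gen_glaucoma_eye(grid, severity = labels[k], seed = seeds[k], id = id, ...)
      }
    }
  } else {
    seeds <- integer(0)
  }
  manifest <- data.frame(
    id = vapply(eyes, function(e) e$id, character(1)),
    cohort = vapply(eyes, function(e) e$cohort, character(1)),
    severity = vapply(eyes, function(e) e$severity, character(1)),
    seed = seeds,
    mean_truth = vapply(eyes, function(e) mean(e$true_thresholds), numeric(1))
  )
  structure(list(eyes = eyes, manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d eyes (%d healthy, %d glaucoma; seed %d)\n",
              length(x$eyes), sum(x$manifest$cohort == "healthy"),
              sum(x$manifest$cohort == "glaucoma"), x$spec$seed))
  invisible(x)
}

#' Cohort text I/O
#'
#' `write_cohort()` writes one bundle per eye (`<id>_thresholds.csv`,
#' `<id>_gcl.txt`, `<id>_geom.csv`) plus `manifest.csv`;
#' `read_cohort()` loads it back.
#'
#' @param cohort A `cohort` from [gen_cohort()].
#' @param dir Output directory (created if missing).
#' @name cohort_io
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in cohort$eyes) write_eye(e, dir)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  eyes <- lapply(manifest$id, function(id) read_eye(dir, id))
  structure(list(eyes = eyes, manifest = manifest, spec = NULL),
            class = "cohort")
}

#' @rdname cohort_io
#' @param eye An [eye_profile()] (needs an `id`).
#' @export
write_eye <- function(eye, dir) {
  stopifnot(!is.null(eye$id))
  utils::write.csv(
    data.frame(index = seq_along(eye$true_thresholds),
               threshold = eye$true_thresholds),
    file.path(dir, paste0(eye$id, "_thresholds.csv")), row.names = FALSE
  )
  if (!is.null(eye$gcl_map)) {
    write_thickness_map(eye$gcl_map, file.path(dir, paste0(eye$id, "_gcl.txt")))
  }
  utils::write.csv(
    data.frame(what = c("fovea", "onh"),
               x = c(eye$fovea[["x"]], eye$onh_center[["x"]]),
               y = c(eye$fovea[["y"]], eye$onh_center[["y"]])),
    file.path(dir, paste0(eye$id, "_geom.csv")), row.names = FALSE
  )
  invisible(dir)
}

#' @rdname cohort_io
#' @param id Eye identifier within `dir`.
#' @export
read_eye <- function(dir, id) {
  th <- utils::read.csv(file.path(dir, paste0(id, "_thresholds.csv")))
  geom <- utils::read.csv(file.path(dir, paste0(id, "_geom.csv")))
  gf <- file.path(dir, paste0(id, "_gcl.txt"))
  map <- if (file.exists(gf)) read_thickness_map(gf) else NULL
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  row <- manifest[manifest$id == id, ]
  eye_profile(th$threshold[order(th$index)], gcl_map = map,
              cohort = row$cohort, severity = row$severity,
              fovea = unlist(geom[geom$what == "fovea", c("x", "y")]),
              onh_center = unlist(geom[geom$what == "onh", c("x", "y")]),
              id = id)
}
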