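#' GCL thickness map container
#'
#' A regularly sampled raster of ganglion cell layer (GCL) thickness in
#' micrometers, on a degree-spaced grid in fundus-reference coordinates.
#' Row 1 is the most superior row; pixel centers are at
#' `x = origin[1] + (col - (ncol+1)/2) * pixel_size` and
#' `y = origin[2] + ((nrow+1)/2 - row) * pixel_size`.
#'
#' @param values Numeric matrix of thickness values, micrometers, in
#'   `[0, 150]`.
#' @param origin Length-2 numeric: degrees of the raster center.
#' @param pixel_size Degrees per pixel (> 0).
#' @return A `thickness_map` object.
#' @export
thickness_map <- function(values, origin = c(0, 0), pixel_size) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(origin) == 2, pixel_size > 0)
  if (anyNA(values) || any(values < 0) || any(values > 150)) {
    stop("thickness values must be finite and within [0, 150] micrometers")
  }
  structure(
    list(values = values,
         origin = c(x = origin[[1]], y = origin[[2]]),
         pixel_size = pixel_size),
    class = "thickness_map"
  )
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf(
    "GCL thickness map: %d x %d px, %.3g deg/px, origin (%.2f, %.2f), range [%.1f, %.1f] um\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$origin[1], x$origin[2],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

# pixel-center coordinate axes of a map (degrees)
map_axes <- function(map) {
  nr <- nrow(map$values); nc <- ncol(map$values)
  list(
    x = map$origin[["x"]] + (seq_len(nc) - (nc + 1) / 2) * map$pixel_size,
    y = map$origin[["y"]] + ((nr + 1) / 2 - seq_len(nr)) * map$pixel_size
  )
}

#' Structure-function model parameters
#'
#' Point-wise macular structure-function model: predicted sensitivity is
#' linear in `log10(GCL thickness)`, `S = intercept + slope * log10(T)`,
#' clamped to the 0-40 dB instrument range. The logistic abnormality map
#' converts the predicted deficit (normative minus predicted sensitivity)
#' into the mixing weight of the abnormal prior component; it is
#' calibrated so that zero deficit reproduces the standard 4:1 mixture
#' (weight 0.2) with the defaults.
#'
#' @param intercept dB.
#' @param slope dB per log10(micrometer); must be positive (thicker GCL
#'   predicts higher sensitivity).
#' @param noise_sd Residual SD of the model, dB.
#' @param mixing_scale Logistic scale of the abnormality map, dB.
#' @param mixing_midpoint Deficit at which the abnormal weight is 0.5, dB.
#'   The default `mixing_scale * log(4)` makes the weight exactly 0.2 at
#'   zero deficit.
#' @return An `sf_params` object.
#' @export
sf_params <- function(intercept = 0, slope = 20, noise_sd = 2,
                      mixing_scale = 2,
                      mixing_midpoint = mixing_scale * log(4)) {
  stopifnot(slope > 0, noise_sd > 0, mixing_scale > 0)
  structure(
    list(intercept = intercept, slope = slope, noise_sd = noise_sd,
         mixing_scale = mixing_scale, mixing_midpoint = mixing_midpoint),
    class = "sf_params"
  )
}

#' Average GCL thickness per test location
#'
#' Averages map pixels whose centers fall within a square window (side
#' `window_deg`) centered on each displaced grid location — the
#' structural measurement paired with each stimulus location after
#' ganglion-cell displacement compensation.
#'
#' @param map A [thickness_map()].
#' @param grid A `vf_grid` (displaced coordinates are used). Grid
#'   coordinates are fovea-relative; the fovea attribute of the grid
#'   places them in the map's frame.
#' @param window_deg Window side, degrees (default 2, one grid cell).
#' @return Data frame with columns `location_index`, `mean_thickness`,
#'   `n_pixels`.
#' @export
sample_gcl <- function(map, grid, window_deg = 2) {
  stopifnot(inherits(map, "thickness_map"), inherits(grid, "vf_grid"),
            window_deg > 0)
  ax <- map_axes(map)
  fov <- attr(grid, "fovea")
  if (anyNA(fov)) fov <- c(x = 0, y = 0)
  half <- window_deg / 2
  out <- data.frame(location_index = grid$index,
                    mean_thickness = NA_real_, n_pixels = NA_integer_)
  for (k in seq_len(nrow(grid))) {
    cx <- grid$x_displaced[k] + fov[["x"]]
    cy <- grid$y_displaced[k] + fov[["y"]]
    jx <- which(abs(ax$x - cx) <= half)
    jy <- which(abs(ax$y - cy) <= half)
    if (length(jx) == 0 || length(jy) == 0 ||
        cx - half < min(ax$x) - map$pixel_size / 2 ||
        cx + half > max(ax$x) + map$pixel_size / 2 ||
        cy - half < min(ax$y) - map$pixel_size / 2 ||
        cy + half > max(ax$y) + map$pixel_size / 2) {
      stop(sprintf(
        "sampling window for location %d (%.2f, %.2f) extends outside the thickness raster",
        grid$index[k], cx, cy
      ))
    }
    px <- map$values[jy, jx, drop = FALSE]
    out$mean_thickness[k] <- mean(px)
    out$n_pixels[k] <- length(px)
  }
  out
}

#' Predict sensitivity from GCL thickness
#'
#' @param thickness Thickness, micrometers (> 0); vectorized.
#' @param params An [sf_params()].
#' @return Predicted sensitivity, dB, clamped to `[0, 40]`.
#' @export
predict_sensitivity <- function(thickness, params = sf_params()) {
  if (any(thickness <= 0)) stop("thickness must be positive")
  pmin(40, pmax(0, params$intercept + params$slope * log10(thickness)))
}

#' Abnormal-component mixing weight from predicted deficit
#'
#' Logistic map of the predicted deficit `d = normative - predicted`:
#' `w = 1 / (1 + exp(-(d - mixing_midpoint) / mixing_scale))`. Large
#' predicted deficits drive the weight toward 1 (mostly abnormal prior
#' mass); thickness well above normal drives it toward 0.
#'
#' @param predicted Predicted sensitivity, dB.
#' @param normative Normative sensitivity, dB.
#' @param params An [sf_params()].
#' @return Weight in `[0, 1]`, vectorized.
#' @export
predict_abnormal_weight <- function(predicted, normative, params = sf_params()) {
  if (params$mixing_scale <= 0) stop("mixing_scale must be positive")
  d <- normative - predicted
  1 / (1 + exp(-(d - params$mixing_midpoint) / params$mixing_scale))
}

#' Fit the structure-function model
#'
#' Ordinary least squares of sensitivity on `log10(thickness)`;
#' `noise_sd` is the residual standard deviation.
#'
#' @param thickness Thickness values, micrometers.
#' @param sensitivity Matching sensitivities, dB.
#' @param mixing_scale,mixing_midpoint Passed through to [sf_params()].
#' @return An [sf_params()] with fitted `intercept`, `slope`, `noise_sd`.
#' @export
fit_sf_model <- function(thickness, sensitivity, mixing_scale = 2,
                         mixing_midpoint = mixing_scale * log(4)) {
  stopifnot(length(thickness) == length(sensitivity))
  if (length(thickness) < 3) stop("need at least 3 pairs")
  if (any(thickness <= 0)) stop("thickness must be positive")
  lt <- log10(thickness)
  if (length(unique(lt)) < 2) stop("degenerate design: all thicknesses equal")
  fit <- stats::lm.fit(cbind(1, lt), sensitivity)
  res_sd <- sqrt(sum(fit$residuals^2) / max(1, length(thickness) - 2))
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted slope is not positive; structure-function model invalid for these data")
  }
  sf_params(intercept = fit$coefficients[[1]], slope = slope,
            noise_sd = max(res_sd, .Machine$double.eps),
            mixing_scale = mixing_scale, mixing_midpoint = mixing_midpoint)
}

#' Thickness map and parameter file I/O
#'
#' Text formats only. A thickness map file is a small header
#' (`# origin_x origin_y pixel_size`) followed by a whitespace-delimited
#' matrix. `read_thickness_pgm()` imports a plain-text PGM (P2) raster,
#' multiplying gray levels by `scale` to get micrometers (supports
#' 16-bit gray ranges). `write_sf_params()`/`read_sf_params()` use a flat
#' `key value` format.
#'
#' @param map A `thickness_map`.
#' @param path File path.
#' @name sf_io
#' @export
write_thickness_map <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %.10g %.10g %.10g",
                     map$origin[["x"]], map$origin[["y"]], map$pixel_size), con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname sf_io
#' @export
read_thickness_map <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#")) stop("missing '# origin_x origin_y pixel_size' header")
  nums <- as.numeric(strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]])
  if (length(nums) != 3) stop("header must contain origin_x origin_y pixel_size")
  vals <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(vals) <- NULL
  thickness_map(vals, origin = nums[1:2], pixel_size = nums[3])
}

#' @rdname sf_io
#' @param scale Micrometers per gray level.
#' @param origin,pixel_size Geometry of the imported raster.
#' @export
read_thickness_pgm <- function(path, scale = 1, origin = c(0, 0), pixel_size) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(toks) < 4 || toks[1] != "P2") stop("not a plain-text PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  thickness_map(matrix(vals * scale, nrow = h, ncol = w, byrow = TRUE),
                origin = origin, pixel_size = pixel_size)
}

#' @rdname sf_io
#' @param params An `sf_params`.
#' @export
write_sf_params <- function(params, path) {
  writeLines(sprintf("%s %.12g", names(unclass(params)),
                     unlist(unclass(params))), path)
  invisible(path)
}

#' @rdname sf_io
#' @export
read_sf_params <- function(path) {
  kv <- utils::read.table(path, col.names = c("key", "value"))
  p <- as.list(stats::setNames(kv$value, kv$key))
  sf_params(intercept = p$intercept, slope = p$slope, noise_sd = p$noise_sd,
            mixing_scale = p$mixing_scale, mixing_midpoint = p$mixing_midpoint)
}
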