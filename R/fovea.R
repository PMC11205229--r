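#' Fovea template
#'
#' A small thickness raster centered on the foveal pit, matched against
#' candidate positions by normalized cross-correlation. Dimensions must
#' be odd so the center pixel is defined.
#'
#' @param raster Numeric matrix, micrometers.
#' @param pixel_size Degrees per pixel.
#' @return A `fovea_template` object.
#' @export
fovea_template <- function(raster, pixel_size) {
  raster <- as.matrix(raster)
  stopifnot(nrow(raster) %% 2 == 1, ncol(raster) %% 2 == 1,
            all(is.finite(raster)), pixel_size > 0)
  structure(list(raster = raster, pixel_size = pixel_size),
            class = "fovea_template")
}

#' Build a fovea template by averaging scans
#'
#' Pixelwise mean of fovea-centered crops of half-width `half_width_deg`
#' from each map. (The clinical analogue averages healthy scans; here
#' any set of maps with known fovea positions can be used, including
#' synthetic pit maps.)
#'
#' @param maps List of [thickness_map()]s, all with the same pixel size.
#' @param half_width_deg Crop half-width, degrees (default 3, enough to
#'   capture the pit).
#' @param centers Optional list/matrix of per-map fovea positions in map
#'   coordinates (degrees); default is `(0, 0)` for every map.
#' @return A [fovea_template()].
#' @export
make_fovea_template <- function(maps, half_width_deg = 3, centers = NULL) {
  stopifnot(length(maps) >= 1)
  ps <- maps[[1]]$pixel_size
  if (is.null(centers)) centers <- rep(list(c(0, 0)), length(maps))
  hw <- round(half_width_deg / ps)
  acc <- NULL
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    if (abs(m$pixel_size - ps) > 1e-9) stop("maps must share a pixel size")
    ax <- map_axes(m)
    ci <- which.min(abs(ax$y - centers[[k]][[2]]))
    cj <- which.min(abs(ax$x - centers[[k]][[1]]))
    if (ci - hw < 1 || ci + hw > nrow(m$values) ||
        cj - hw < 1 || cj + hw > ncol(m$values)) {
      stop(sprintf("map %d does not cover the template window", k))
    }
    crop <- m$values[(ci - hw):(ci + hw), (cj - hw):(cj + hw)]
    acc <- if (is.null(acc)) crop else acc + crop
  }
  fovea_template(acc / length(maps), pixel_size = ps)
}

#' Locate the fovea by normalized cross-correlation
#'
#' Slides the template over the map and returns the placement with the
#' maximum zero-normalized cross-correlation (Pearson correlation of
#' template and window pixels), restricted to placements whose center
#' lies within a square search region (default 12.5 degrees x 12.5
#' degrees, i.e. half-width 6.25). Ties are broken by distance to the
#' search center, then row-major order. The score is invariant to
#' affine intensity rescaling of the map.
#'
#' @param map A [thickness_map()].
#' @param template A [fovea_template()] with the same pixel size.
#' @param search_center Length-2 degrees, center of the search region.
#' @param search_half_width Degrees (default 6.25).
#' @return List with `x`, `y` (degrees, map frame) and `score` in
#'   `[-1, 1]`.
#' @export
locate_fovea <- function(map, template, search_center = c(0, 0),
                         search_half_width = 6.25) {
  stopifnot(inherits(map, "thickness_map"), inherits(template, "fovea_template"))
  if (abs(map$pixel_size - template$pixel_size) > 1e-9) {
    stop("map and template pixel sizes differ")
  }
  t_raster <- template$raster
  t_vec <- as.vector(t_raster)
  if (stats::sd(t_vec) == 0) stop("flat template: NCC undefined")
  hr <- (nrow(t_raster) - 1) / 2
  hc <- (ncol(t_raster) - 1) / 2
  ax <- map_axes(map)
  # candidate centers: inside the search region AND far enough from the
  # borders for a full template window
  rows <- which(abs(ax$y - search_center[[2]]) <= search_half_width)
  cols <- which(abs(ax$x - search_center[[1]]) <= search_half_width)
  rows <- rows[rows > hr & rows <= nrow(map$values) - hr]
  cols <- cols[cols > hc & cols <= ncol(map$values) - hc]
  if (length(rows) == 0 || length(cols) == 0) {
    stop("search region does not fit inside the raster")
  }
  t_c <- t_vec - mean(t_vec)
  t_norm <- sqrt(sum(t_c^2))
  best <- -Inf; best_i <- NA; best_j <- NA; best_d <- Inf
  for (i in rows) {
    for (j in cols) {
      w <- map$values[(i - hr):(i + hr), (j - hc):(j + hc)]
      wv <- as.vector(w)
      wc <- wv - mean(wv)
      wn <- sqrt(sum(wc^2))
      if (wn == 0) stop("flat map window: NCC undefined")
      sc <- sum(wc * t_c) / (wn * t_norm)
      d <- (ax$x[j] - search_center[[1]])^2 + (ax$y[i] - search_center[[2]])^2
      if (sc > best + 1e-12 || (abs(sc - best) <= 1e-12 && d < best_d)) {
        best <- sc; best_i <- i; best_j <- j; best_d <- d
      }
    }
  }
  list(x = ax$x[best_j], y = ax$y[best_i], score = best)
}

#' Synthetic foveal pit map
#'
#' A stand-in for real macular scans (which cannot be redistributed): a
#' uniform GCL mound with a radially Gaussian pit of depth `pit_depth`
#' and width `pit_sigma` at a known position, plus optional pixel noise
#' drawn from the current R random stream.
#'
#' @param fovea Length-2 degrees, true pit position.
#' @param base Background thickness, micrometers.
#' @param pit_depth Pit depth, micrometers.
#' @param pit_sigma Pit Gaussian SD, degrees.
#' @param noise_sd Additive pixel noise SD, micrometers.
#' @param half_extent,pixel_size Raster geometry, degrees.
#' @return A [thickness_map()].
#' @export
synthetic_pit_map <- function(fovea = c(0, 0), base = 60, pit_depth = 40,
                              pit_sigma = 1, noise_sd = 0,
                              half_extent = 10, pixel_size = 0.25) {
  ax <- seq(-half_extent, half_extent, by = pixel_size)
  xg <- outer(rep(1, length(ax)), ax)
  yg <- outer(rev(ax), rep(1, length(ax)))
  r2 <- (xg - fovea[[1]])^2 + (yg - fovea[[2]])^2
  v <- base - pit_depth * exp(-r2 / (2 * pit_sigma^2))
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  v <- matrix(pmin(150, pmax(0, v)), nrow(v), ncol(v))
  thickness_map(v, origin = c(0, 0), pixel_size = pixel_size)
}

#' Affine transform between coordinate frames
#'
#' Maps OCT raster coordinates into the fundus reference frame (or any
#' 2-D degree frame into another): `x' = A x + b`. The registration
#' that estimates `A`, `b` is external; this object only stores and
#' applies it.
#'
#' @param A 2x2 numeric matrix, invertible.
#' @param b Length-2 numeric offset, degrees.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(A = diag(2), b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  stopifnot(length(b) == 2)
  if (abs(det(A)) <= 1e-9) stop("affine linear part is singular")
  structure(list(A = A, b = as.numeric(b)), class = "affine_transform")
}

#' Apply (or invert) an affine transform to points
#'
#' @param points Numeric matrix or data frame with two columns (x, y),
#'   or a length-2 vector.
#' @param t An [affine_transform()].
#' @return Matrix of transformed points, columns `x`, `y`.
#' @export
apply_affine <- function(points, t) {
  stopifnot(inherits(t, "affine_transform"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  out <- p %*% t(t$A) + matrix(t$b, nrow(p), 2, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' @rdname apply_affine
#' @export
invert_affine <- function(t) {
  Ai <- solve(t$A)
  affine_transform(Ai, -Ai %*% t$b)
}

#' Affine transform file I/O: six numbers, row-major (a11 a12 a21 a22 b1 b2)
#'
#' @param t An [affine_transform()].
#' @param path File path.
#' @name affine_io
#' @export
write_affine <- function(t, path) {
  writeLines(paste(c(t(t$A), t$b), collapse = " "), path)
  invisible(path)
}

#' @rdname affine_io
#' @export
read_affine <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 6) stop("affine file must contain six numbers")
  affine_transform(matrix(v[1:4], 2, 2, byrow = TRUE), v[5:6])
}
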