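#' Build the 68-location 10-2 test grid
#'
#' Constructs the standard 10-2 perimetric pattern: all odd-integer
#' degree coordinates `(x, y)` with `|x|, |y| <= 9` satisfying
#' `x^2 + y^2 <= 85`, which yields exactly 68 locations at 2 degree
#' spacing within the central 10 degrees. Coordinates are fovea-centered
#' visual degrees in right-eye convention (x positive temporal, y
#' positive superior).
#'
#' Locations are ordered row-major: superior to inferior (decreasing y),
#' then nasal to temporal (increasing x) within each row.
#'
#' @return A `vf_grid` object: a data frame with columns `index`,
#'   `x_nominal`, `y_nominal` (canonical unrotated pattern), `x`, `y`
#'   (current, possibly rotated, pre-displacement coordinates) and
#'   `x_displaced`, `y_displaced` (after ganglion-cell displacement;
#'   initially equal to `x`, `y`). Attributes `rotation_deg`, `fovea`
#'   and `onh_center` record the geometry.
#' @seealso [rotate_grid()], [displace_locations()], [build_neighbor_graph()]
#' @export
#' @examples
#' g <- build_10_2_grid()
#' nrow(g)   # 68
build_10_2_grid <- function() {
  odd <- seq(-9L, 9L, by = 2L)
  pts <- expand.grid(x = odd, y = odd)
  pts <- pts[pts$x^2 + pts$y^2 <= 85, , drop = FALSE]
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  g <- data.frame(
    index = seq_len(nrow(pts)),
    x_nominal = as.numeric(pts$x), y_nominal = as.numeric(pts$y),
    x = as.numeric(pts$x), y = as.numeric(pts$y),
    x_displaced = as.numeric(pts$x), y_displaced = as.numeric(pts$y)
  )
  rownames(g) <- NULL
  structure(g,
    rotation_deg = 0,
    fovea = c(x = 0, y = 0),
    onh_center = c(x = NA_real_, y = NA_real_),
    class = c("vf_grid", "data.frame")
  )
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf(
    "10-2 test grid: %d locations, rotation %.2f deg\n",
    nrow(x), attr(x, "rotation_deg")
  ))
  NextMethod()
}

#' Rotate the grid along the fovea-disc axis
#'
#' Rotates the nominal grid about the fovea so that the horizontal
#' midline of the pattern is oriented along the axis from the fovea to
#' the optic nerve head (ONH) center. The rotation angle is the angle of
#' the fovea-to-ONH vector relative to horizontal.
#'
#' @param grid A `vf_grid` from [build_10_2_grid()].
#' @param fovea Numeric length-2, fovea position in fundus-reference degrees.
#' @param onh_center Numeric length-2, ONH center in the same frame.
#' @return The grid with `x`, `y` rotated (fovea-relative), displaced
#'   coordinates reset to the rotated positions, and geometry attributes set.
#' @export
rotate_grid <- function(grid, fovea, onh_center) {
  stopifnot(inherits(grid, "vf_grid"), length(fovea) == 2, length(onh_center) == 2)
  dx <- onh_center[[1]] - fovea[[1]]
  dy <- onh_center[[2]] - fovea[[2]]
  if (dx == 0 && dy == 0) {
    stop("fovea and ONH center coincide: fovea-disc axis is degenerate")
  }
  theta <- atan2(dy, dx)
  ct <- cos(theta); st <- sin(theta)
  x <- grid$x_nominal; y <- grid$y_nominal
  grid$x <- ct * x - st * y
  grid$y <- st * x + ct * y
  grid$x_displaced <- grid$x
  grid$y_displaced <- grid$y
  attr(grid, "rotation_deg") <- theta * 180 / pi
  attr(grid, "fovea") <- c(x = fovea[[1]], y = fovea[[2]])
  attr(grid, "onh_center") <- c(x = onh_center[[1]], y = onh_center[[2]])
  grid
}

#' Parametric ganglion-cell displacement model
#'
#' In the central macula, retinal ganglion cells (RGCs) are laterally
#' displaced from the photoreceptors they serve, so a stimulus location
#' must be mapped outward (centrifugally) to the retinal position of its
#' underlying RGCs before sampling structural measurements. The default
#' is a radial parametric curve with the canonical Drasdo-like shape:
#' zero at the fovea, peak displacement `d_max` at eccentricity
#' `ecc_peak`, smooth decay, and identically zero at or beyond `extent`.
#'
#' The displacement magnitude is
#' `d(r) = d_max * (r / ecc_peak) * exp(1 - r / ecc_peak)` for
#' `r < extent`, 0 otherwise; the displaced eccentricity is `r + d(r)`
#' along the same radial direction.
#'
#' @param d_max Peak displacement, degrees (default 2).
#' @param ecc_peak Eccentricity of peak displacement, degrees (default 1.5).
#' @param extent Eccentricity beyond which displacement is exactly 0
#'   (default 17).
#' @return A `displacement_model` object (callable on eccentricity in
#'   degrees, returning displacement magnitude in degrees).
#' @export
drasdo_displacement <- function(d_max = 2, ecc_peak = 1.5, extent = 17) {
  stopifnot(d_max >= 0, ecc_peak > 0, extent > 0)
  f <- function(r) {
    d <- d_max * (r / ecc_peak) * exp(1 - r / ecc_peak)
    d[r >= extent] <- 0
    d
  }
  structure(f,
    d_max = d_max, ecc_peak = ecc_peak, extent = extent,
    class = c("displacement_model", "function")
  )
}

#' Apply ganglion-cell displacement to grid locations
#'
#' Maps each (possibly rotated) stimulus location radially away from the
#' fovea according to a displacement model, storing the result in the
#' `x_displaced`, `y_displaced` columns. Locations at the fovea or beyond
#' the model's extent are unchanged.
#'
#' @param grid A `vf_grid`.
#' @param model A [drasdo_displacement()] model (or any function of
#'   eccentricity returning displacement magnitude in degrees).
#' @return The grid with displaced coordinates filled in.
#' @export
displace_locations <- function(grid, model = drasdo_displacement()) {
  stopifnot(inherits(grid, "vf_grid"), is.function(model))
  r <- sqrt(grid$x^2 + grid$y^2)
  d <- model(r)
  scale <- ifelse(r > 0, (r + d) / r, 1)
  grid$x_displaced <- grid$x * scale
  grid$y_displaced <- grid$y * scale
  grid
}

#' Build the strategy neighbor graph
#'
#' Connects nearest neighbors (nominal grid distance exactly 2 degrees,
#' i.e. 4-adjacency on the unrotated pattern) and assigns the spatial
#' correlation strength used to down-weight likelihood propagation.
#'
#' In `standard` mode (ZEST) the weight is 0.2 and edges crossing the
#' horizontal midline (opposite sign of nominal y) are removed. In
#' `structural` mode (S-ZEST) the weight is 0.4 and an edge is removed
#' when the structure-function predicted sensitivities of its endpoints
#' differ by more than 1 dB.
#'
#' @param grid A `vf_grid`.
#' @param mode `"standard"` or `"structural"`.
#' @param predictions Numeric vector of 68 predicted sensitivities (dB);
#'   required in structural mode.
#' @param weight Override the per-mode default correlation strength.
#' @param pred_cut_db Prediction-difference disconnection threshold,
#'   structural mode (default 1 dB).
#' @return A `neighbor_graph`: data frame with columns `i`, `j`
#'   (`i < j`) and `weight`, plus an attribute `mode`.
#' @export
build_neighbor_graph <- function(grid, mode = c("standard", "structural"),
                                 predictions = NULL, weight = NULL,
                                 pred_cut_db = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "vf_grid"))
  n <- nrow(grid)
  if (mode == "structural") {
    if (is.null(predictions) || length(predictions) != n || anyNA(predictions)) {
      stop("structural mode requires a prediction (dB) for every location")
    }
  }
  if (is.null(weight)) weight <- if (mode == "standard") 0.2 else 0.4
  x <- grid$x_nominal; y <- grid$y_nominal
  pairs <- which(
    outer(x, x, function(a, b) abs(a - b)) +
      outer(y, y, function(a, b) abs(a - b)) == 2,
    arr.ind = TRUE
  )
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- if (mode == "standard") {
    sign(y[i]) == sign(y[j])
  } else {
    abs(predictions[i] - predictions[j]) <= pred_cut_db
  }
  edges <- data.frame(i = i[keep], j = j[keep], weight = weight)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, mode = mode, n_locations = n,
            class = c("neighbor_graph", "data.frame"))
}

#' Neighbor lookup list for a graph
#'
#' @param graph A `neighbor_graph`.
#' @return List of length `n_locations`; element k is an integer vector
#'   of the neighbors of location k.
#' @keywords internal
neighbor_list <- function(graph) {
  n <- attr(graph, "n_locations")
  nb <- vector("list", n)
  for (k in seq_len(nrow(graph))) {
    i <- graph$i[k]; j <- graph$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Grid and graph text I/O
#'
#' `write_grid()`/`read_grid()` round-trip a grid as delimited text with
#' columns `index,x_nominal,y_nominal,x_displaced,y_displaced` (plus the
#' current rotated coordinates). `write_edges()` exports a neighbor graph
#' as an `i,j,weight` edge list.
#'
#' @param grid A `vf_grid`.
#' @param path File path.
#' @name grid_io
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_grid <- function(path) {
  d <- utils::read.csv(path)
  need <- c("index", "x_nominal", "y_nominal", "x_displaced", "y_displaced")
  if (!all(need %in% names(d))) {
    stop("grid file missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (is.null(d$x)) d$x <- d$x_nominal
  if (is.null(d$y)) d$y <- d$y_nominal
  structure(d[c("index", "x_nominal", "y_nominal", "x", "y",
                "x_displaced", "y_displaced")],
    rotation_deg = 0, fovea = c(x = 0, y = 0),
    onh_center = c(x = NA_real_, y = NA_real_),
    class = c("vf_grid", "data.frame")
  )
}

#' @rdname grid_io
#' @param graph A `neighbor_graph`.
#' @export
write_edges <- function(graph, path) {
  utils::write.csv(as.data.frame(graph), path, row.names = FALSE)
  invisible(path)
}
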