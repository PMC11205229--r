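test_that("sample_gcl averages the pixels under each window", {
  g <- the_grid
  # constant map: every mean equals the constant
  mc <- thickness_map(matrix(42, 121, 121), pixel_size = 0.25)
  s <- sample_gcl(mc, g)
  expect_equal(s$mean_thickness, rep(42, 68))
  expect_true(all(s$n_pixels >= 1))

  # step map: left half 20, right half 60; a window straddling the step
  # equally averages to 40 (checked via a location whose displaced x is 0)
  vals <- matrix(20, 121, 121)
  vals[, 62:121] <- 60  # step at x = 0.125; x axis: cols 1..121 -> -15..15
  ms <- thickness_map(vals, pixel_size = 0.25)
  g0 <- build_10_2_grid()
  # window centered at x = 0.125 covers 4 px at 20 and 4 px at 60 per row
  g0$x_displaced[1] <- 0.125; g0$y_displaced[1] <- 0.125
  s2 <- sample_gcl(ms, g0)
  expect_equal(s2$mean_thickness[1], 40)

  # 2x2-pixel window mean: values 10,20,30,40 -> 25
  m4 <- thickness_map(matrix(c(10, 20, 30, 40), 2, 2), pixel_size = 1)
  g1 <- g0[1, , drop = FALSE]
  class(g1) <- class(g0); attr(g1, "fovea") <- c(x = 0, y = 0)
  g1$x_displaced <- 0; g1$y_displaced <- 0
  s3 <- sample_gcl(m4, g1, window_deg = 2)
  expect_equal(s3$mean_thickness, 25)
  expect_equal(s3$n_pixels, 4L)

  # window outside the raster names the offending location
  tiny <- thickness_map(matrix(30, 10, 10), pixel_size = 0.25)
  expect_error(sample_gcl(tiny, g), "location")
})

test_that("means are bounded by the sampled pixels", {
  set.seed(5)
  vals <- matrix(runif(121^2, 10, 90), 121, 121)
  m <- thickness_map(vals, pixel_size = 0.25)
  s <- sample_gcl(m, the_grid)
  expect_true(all(s$mean_thickness >= min(vals) & s$mean_thickness <= max(vals)))
})

test_that("predict_sensitivity is the clamped log10 line", {
  p <- sf_params(intercept = 0, slope = 20)
  expect_equal(predict_sensitivity(31.6, p), 20 * log10(31.6), tolerance = 1e-12)
  expect_equal(predict_sensitivity(31.6, p), 30, tolerance = 0.01)
  # inversion of the line hits the 40 dB ceiling exactly
  expect_equal(predict_sensitivity(10^((40 - p$intercept) / p$slope), p), 40)
  expect_equal(predict_sensitivity(10^3, p), 40)  # clamped above
  expect_equal(predict_sensitivity(0.5, p), 0)    # clamped below
  # monotone nondecreasing
  th <- seq(0.5, 140, by = 0.5)
  expect_true(all(diff(predict_sensitivity(th, p)) >= 0))
  expect_error(predict_sensitivity(0, p), "positive")
})

test_that("abnormal weight is a calibrated logistic in the deficit", {
  p <- sf_params()
  # zero deficit reproduces the 4:1 mixture's abnormal fraction
  expect_equal(predict_abnormal_weight(30, 30, p), 0.2, tolerance = 1e-12)
  # midpoint and limits
  expect_equal(predict_abnormal_weight(30 - p$mixing_midpoint, 30, p), 0.5)
  expect_equal(predict_abnormal_weight(70, 30, p), 0, tolerance = 1e-6)
  expect_equal(predict_abnormal_weight(-40, 30, p), 1, tolerance = 1e-6)
  # monotone increasing in deficit
  w <- predict_abnormal_weight(seq(40, 0, by = -1), 30, p)
  expect_true(all(diff(w) > 0))
  expect_error(predict_abnormal_weight(30, 30, sf_params(mixing_scale = 1e-9)),
               NA)  # tiny but positive scale is allowed
  expect_error(sf_params(mixing_scale = 0))
})

test_that("fit_sf_model recovers parameters", {
  t <- c(10, 20, 40, 60, 80, 100)
  s <- 5 + 18 * log10(t)
  fit <- fit_sf_model(t, s)
  expect_equal(fit$slope, 18, tolerance = 1e-8)
  expect_equal(fit$intercept, 5, tolerance = 1e-8)
  expect_lt(fit$noise_sd, 1e-7)

  # duplication invariance of OLS
  fit2 <- fit_sf_model(c(t, t), c(s, s))
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept, tolerance = 1e-10)

  # noisy Monte-Carlo recovery: slope within +/- 0.5 at n = 500, sd = 2
  set.seed(101)
  tn <- runif(500, 10, 100)
  sn <- 5 + 18 * log10(tn) + rnorm(500, 0, 2)
  fitn <- fit_sf_model(tn, sn)
  expect_lt(abs(fitn$slope - 18), 0.5)
  expect_equal(fitn$noise_sd, 2, tolerance = 0.3)

  expect_error(fit_sf_model(c(10, 10, 10), c(1, 2, 3)), "degenerate")
  expect_error(fit_sf_model(c(10, 20), c(1, 2)), "at least 3")
})

test_that("thickness map, PGM and params round-trip through text", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  m <- thickness_map(matrix(seq(10, 40, length.out = 12), 3, 4),
                     origin = c(1, -2), pixel_size = 0.5)
  write_thickness_map(m, tmp)
  m2 <- read_thickness_map(tmp)
  expect_equal(m2$values, m$values, tolerance = 1e-9)
  expect_equal(m2$origin, m$origin)
  expect_equal(m2$pixel_size, 0.5)

  pgm <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "3 2", "65535", "100 200 300", "400 500 600"), pgm)
  mp <- read_thickness_pgm(pgm, scale = 0.1, pixel_size = 0.25)
  expect_equal(mp$values, matrix(c(10, 40, 20, 50, 30, 60), 2, 3))

  pf <- withr::local_tempfile(fileext = ".cfg")
  p <- sf_params(intercept = 1.5, slope = 22, noise_sd = 1.7)
  write_sf_params(p, pf)
  p2 <- read_sf_params(pf)
  expect_equal(p2$slope, 22)
  expect_equal(p2$mixing_midpoint, p$mixing_midpoint, tolerance = 1e-9)

  expect_error(thickness_map(matrix(-1, 2, 2), pixel_size = 1), "150|\\[0")
  expect_error(thickness_map(matrix(200, 2, 2), pixel_size = 1))
})
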