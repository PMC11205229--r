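test_that("10-2 grid has the standard 68-point pattern", {
  g <- build_10_2_grid()
  expect_s3_class(g, "vf_grid")
  expect_equal(nrow(g), 68)
  pts <- paste(g$x_nominal, g$y_nominal)
  for (p in list(c(1, 1), c(9, 1), c(1, 9), c(5, 7))) {
    expect_true(paste(p[1], p[2]) %in% pts)
  }
  for (p in list(c(3, 9), c(7, 7), c(9, 3))) {
    expect_false(paste(p[1], p[2]) %in% pts)
  }
  # reflection symmetry in either axis
  expect_setequal(pts, paste(-g$x_nominal, g$y_nominal))
  expect_setequal(pts, paste(g$x_nominal, -g$y_nominal))
  # deterministic ordering: superior-to-inferior, then left-to-right
  expect_true(all(diff(g$y_nominal) <= 0))
  expect_equal(g$index, seq_len(68))
})

test_that("rotation follows the fovea-disc axis and preserves distances", {
  g <- build_10_2_grid()
  # ONH on the positive x-axis of the fovea: identity rotation
  r0 <- rotate_grid(g, fovea = c(0, 0), onh_center = c(15, 0))
  expect_equal(r0$x, g$x_nominal)
  expect_equal(attr(r0, "rotation_deg"), 0)

  # axis at +10 degrees: point (9,1) lands at angle atan2(1,9) + 10 deg,
  # radius sqrt(82) (closed-form 2-D rotation)
  th <- 10 * pi / 180
  r10 <- rotate_grid(g, fovea = c(0, 0), onh_center = c(15 * cos(th), 15 * sin(th)))
  k <- which(g$x_nominal == 9 & g$y_nominal == 1)
  ang <- atan2(1, 9) + th
  expect_equal(r10$x[k], sqrt(82) * cos(ang), tolerance = 1e-12)
  expect_equal(r10$y[k], sqrt(82) * sin(ang), tolerance = 1e-12)

  # pairwise distances preserved
  d0 <- dist(cbind(g$x_nominal, g$y_nominal))
  d1 <- dist(cbind(r10$x, r10$y))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  # rotating by theta then -theta restores the nominal grid
  back <- rotate_grid(r10, fovea = c(0, 0), onh_center = c(15, 0))
  expect_equal(back$x, g$x_nominal, tolerance = 1e-12)

  expect_error(rotate_grid(g, c(1, 2), c(1, 2)), "degenerate")
})

test_that("ganglion-cell displacement is radial, centrifugal and bounded", {
  model <- drasdo_displacement()
  expect_equal(model(0), 0)              # continuity at the fovea
  expect_equal(model(20), 0)             # identity beyond the extent
  expect_equal(model(17), 0)
  # default curve: peak ~2 deg at ~1.5 deg eccentricity
  expect_equal(model(1.5), 2)
  expect_gt(1 + model(1), 2)             # 1 deg input maps beyond 1 deg
  # monotone decay beyond the peak
  r <- seq(2, 16.9, by = 0.1)
  expect_true(all(diff(model(r)) < 0))

  g <- displace_locations(build_10_2_grid(), model)
  ecc0 <- sqrt(g$x^2 + g$y^2)
  ecc1 <- sqrt(g$x_displaced^2 + g$y_displaced^2)
  expect_true(all(ecc1 >= ecc0))
  expect_equal(ecc1, ecc0 + model(ecc0), tolerance = 1e-12)
  # angles unchanged (radial displacement)
  expect_equal(atan2(g$y_displaced, g$x_displaced), atan2(g$y, g$x),
               tolerance = 1e-12)
})

test_that("standard neighbor graph is 2-degree adjacency split at the midline", {
  g <- build_10_2_grid()
  gr <- build_neighbor_graph(g, "standard")
  expect_true(all(gr$weight == 0.2))
  expect_true(all(gr$i < gr$j))
  key <- function(a, b) {
    ia <- which(g$x_nominal == a[1] & g$y_nominal == a[2])
    ib <- which(g$x_nominal == b[1] & g$y_nominal == b[2])
    any((gr$i == min(ia, ib)) & (gr$j == max(ia, ib)))
  }
  expect_true(key(c(1, 1), c(3, 1)))
  expect_false(key(c(1, 1), c(1, -1)))   # disconnected across the midline
  # exactly a superior and an inferior component
  same_hemi <- sign(g$y_nominal[gr$i]) == sign(g$y_nominal[gr$j])
  expect_true(all(same_hemi))
  # every within-hemifield 2-degree pair is present
  n_expected <- sum(
    (abs(outer(g$x_nominal, g$x_nominal, "-")) +
       abs(outer(g$y_nominal, g$y_nominal, "-")) == 2) &
      outer(sign(g$y_nominal), sign(g$y_nominal), "==")
  ) / 2
  expect_equal(nrow(gr), n_expected)
})

test_that("structural graph disconnects on >1 dB prediction differences", {
  g <- build_10_2_grid()
  pred <- rep(25, 68)
  i11 <- which(g$x_nominal == 1 & g$y_nominal == 1)
  i31 <- which(g$x_nominal == 3 & g$y_nominal == 1)

  pred2 <- pred; pred2[i31] <- 25 + 1.5
  gr <- build_neighbor_graph(g, "structural", predictions = pred2)
  expect_false(any(gr$i == min(i11, i31) & gr$j == max(i11, i31)))

  pred3 <- pred; pred3[i31] <- 25 + 0.5
  gr3 <- build_neighbor_graph(g, "structural", predictions = pred3)
  expect_true(any(gr3$i == min(i11, i31) & gr3$j == max(i11, i31)))
  expect_true(all(gr3$weight == 0.4))

  # identical predictions: full 2-degree adjacency, no midline cut
  gr_flat <- build_neighbor_graph(g, "structural", predictions = pred)
  n_adj <- sum(abs(outer(g$x_nominal, g$x_nominal, "-")) +
                 abs(outer(g$y_nominal, g$y_nominal, "-")) == 2) / 2
  expect_equal(nrow(gr_flat), n_adj)
  expect_gt(nrow(gr_flat), nrow(build_neighbor_graph(g, "standard")))

  expect_error(build_neighbor_graph(g, "structural"), "prediction")
})

test_that("grid and edge-list round-trip through text files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  g <- displace_locations(rotate_grid(build_10_2_grid(), c(0, 0), c(15, -1.5)))
  write_grid(g, tmp)
  g2 <- read_grid(tmp)
  expect_equal(g2$x_displaced, g$x_displaced, tolerance = 1e-9)
  expect_equal(g2$y_nominal, g$y_nominal)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  gr <- build_neighbor_graph(g, "standard")
  write_edges(gr, tmp2)
  back <- utils::read.csv(tmp2)
  expect_equal(back$i, gr$i)
  expect_equal(back$weight, gr$weight)
})
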