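test_that("likelihood is the asymptoted Gaussian cdf", {
  dom <- zest_domain()
  cfg <- strategy_config()
  L <- likelihood_seen(20, dom, cfg)
  expect_equal(L[dom == 20], 0.5)                       # 0.03 + 0.94 * 1/2
  expect_equal(L[dom == 21], 0.03 + 0.94 * pnorm(1), tolerance = 1e-12)
  expect_equal(L[dom == 40], 0.97, tolerance = 1e-6)    # upper asymptote
  expect_equal(L[dom == 0], 0.03, tolerance = 1e-6)     # lower asymptote
  # increasing (strictly so away from double-precision tail saturation)
  expect_true(all(diff(L) >= 0))
  expect_true(all(diff(L[dom >= 12 & dom <= 28]) > 0))
})

test_that("update_pdf is Bayes' rule with the response likelihood", {
  dom3 <- c(10, 20, 30)
  p <- discrete_pdf(dom3, c(0.2, 0.5, 0.3))
  post <- update_pdf(p, 20, TRUE)
  # independent arithmetic oracle
  L <- 0.03 + 0.94 * pnorm((dom3 - 20) / 1)
  w <- c(0.2, 0.5, 0.3) * L
  expect_equal(post$mass, w / sum(w), tolerance = 1e-12)

  # seen shifts the mean up, not-seen down
  u <- discrete_pdf(zest_domain(), rep(1, 41))
  expect_gt(pdf_mean(update_pdf(u, 20, TRUE)), 20)
  expect_lt(pdf_mean(update_pdf(u, 20, FALSE)), 20)

  # degenerate prior is a fixed point
  m <- rep(0, 41); m[21] <- 1
  pt <- discrete_pdf(zest_domain(), m)
  expect_equal(update_pdf(pt, 25, FALSE)$mass, m)

  # repeated updates never zero out the pdf (asymptotes > 0)
  q <- discrete_pdf(zest_domain(), rep(1, 41))
  for (k in 1:50) q <- update_pdf(q, 40, TRUE)
  expect_true(all(q$mass > 0))
  expect_equal(sum(q$mass), 1, tolerance = 1e-9)
})

test_that("spatial update flattens the likelihood by the edge weight", {
  dom <- zest_domain()
  g <- build_10_2_grid()
  pred <- rep(25, 68)
  gr <- build_neighbor_graph(g, "structural", predictions = pred)  # w = 0.4
  states <- lapply(1:68, function(k) {
    list(pdf = discrete_pdf(dom, rep(1, 41)), terminated = FALSE)
  })
  i11 <- which(g$x_nominal == 1 & g$y_nominal == 1)
  nb <- c(gr$j[gr$i == i11], gr$i[gr$j == i11])
  expect_true(length(nb) >= 3)

  out <- spatial_update(states, gr, i11, 20, TRUE)
  # tested location: full update
  expect_equal(out[[i11]]$pdf$mass, update_pdf(states[[i11]]$pdf, 20, TRUE)$mass)
  # neighbor: renormalized (1 - w) + w * L against hand computation
  L <- 0.03 + 0.94 * pnorm(dom - 20)
  Lw <- 0.6 + 0.4 * L
  expect_equal(out[[nb[1]]]$pdf$mass, Lw / sum(Lw), tolerance = 1e-12)
  # unconnected location untouched
  far <- which(g$x_nominal == 1 & g$y_nominal == -9)
  expect_equal(out[[far]]$pdf$mass, states[[far]]$pdf$mass)

  # terminated neighbors are skipped
  states[[nb[1]]]$terminated <- TRUE
  out2 <- spatial_update(states, gr, i11, 20, TRUE)
  expect_equal(out2[[nb[1]]]$pdf$mass, states[[nb[1]]]$pdf$mass)

  # w = 1 edge: neighbor update equals the full update
  gr1 <- gr; gr1$weight[] <- 1
  out3 <- spatial_update(states, gr1, i11, 20, FALSE)
  expect_equal(out3[[nb[2]]]$pdf$mass,
               update_pdf(states[[nb[2]]]$pdf, 20, FALSE)$mass,
               tolerance = 1e-12)
  # w = 0 edge: neighbor unchanged
  gr0 <- gr; gr0$weight[] <- 0
  out4 <- spatial_update(states, gr0, i11, 20, TRUE)
  expect_equal(out4[[nb[2]]]$pdf$mass, states[[nb[2]]]$pdf$mass,
               tolerance = 1e-12)
})

test_that("stimulus selection is the rounded, clipped posterior mean", {
  dom <- zest_domain()
  expect_equal(select_stimulus(discrete_pdf(dom, rep(1, 41))), 20)
  m <- rep(0, 41); m[34] <- 1
  expect_equal(select_stimulus(discrete_pdf(dom, m)), 33)
  # round-half-even at the stimulus quantum
  two <- rep(0, 41); two[c(11, 31)] <- c(0.48, 0.52)  # mean 20.4
  expect_equal(select_stimulus(discrete_pdf(dom, two)), 20)
  half <- rep(0, 41); half[c(21, 22)] <- 0.5          # mean 20.5 -> even
  expect_equal(select_stimulus(discrete_pdf(dom, half)), 20)
})

test_that("termination uses the inclusive 1.5 dB posterior-SD bound", {
  dom <- zest_domain()
  cfg <- strategy_config()
  m <- rep(0, 41); m[21] <- 1
  expect_true(is_terminated(discrete_pdf(dom, m), cfg))       # sd 0
  expect_false(is_terminated(discrete_pdf(dom, rep(1, 41)), cfg))  # sd ~11.83
  b <- rep(0, 41); b[c(20, 23)] <- 0.5                        # 19 and 22: sd 1.5
  expect_true(is_terminated(discrete_pdf(dom, b), cfg))       # boundary inclusive
})

test_that("single-location run matches the exhaustive Bayes oracle", {
  # 5-bin domain, scripted responses; the oracle recomputes every step
  # with plain arithmetic (helper), independent of the engine functions
  mass <- rep(0.2, 5)
  responses <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  p <- discrete_pdf(domain5, mass)
  cfg <- strategy_config()
  for (resp in responses) {
    stim_pkg <- select_stimulus(p, cfg)
    stim_orc <- min(max(round(oracle_mean(mass, domain5)), 0), 40)
    expect_identical(stim_pkg, stim_orc)
    p <- update_pdf(p, stim_pkg, resp, cfg)
    mass <- oracle_bayes_step(mass, domain5, stim_orc, resp)
    expect_equal(p$mass, mass, tolerance = 1e-12)
    expect_equal(pdf_sd(p), oracle_sd(mass, domain5), tolerance = 1e-9)
  }
})

test_that("run_test converges to the truth with a deterministic observer", {
  g <- the_grid
  # truth equal to the prior modes (integer domain points), noiseless
  # observer: estimates land within 1 dB of the truth everywhere
  truth <- round(make_normative_map(g))
  eye <- eye_profile(truth, cohort = "healthy")
  res <- run_test(eye, g, observer = deterministic_observer(),
                  normative = truth, seed = 11)
  expect_true(all(res$per_location$terminated | res$per_location$capped))
  expect_lte(max(abs(res$estimates - truth)), 1)
  expect_true(all(res$estimates >= 0 & res$estimates <= 40))
  expect_equal(res$n_presentations, sum(res$per_location$n_presentations))
  expect_equal(res$duration_model_s, res$n_presentations * 1.6)
  expect_equal(nrow(res$trace), res$n_presentations)
})

test_that("run_test is bit-identical under a fixed seed", {
  g <- the_grid
  eye <- gen_healthy_eye(g, seed = 300)
  a <- run_test(eye, g, seed = 77)
  b <- run_test(eye, g, seed = 77)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$trace, b$trace)
  c2 <- run_test(eye, g, seed = 78)
  expect_false(identical(a$trace, c2$trace))
})

test_that("priors peaked at the truth need no more presentations", {
  g <- the_grid
  truth <- rep(20, 68)
  eye <- eye_profile(truth, cohort = "healthy")
  dom <- zest_domain()
  on_peak <- lapply(truth, make_standard_prior, domain = dom)
  off_peak <- lapply(rep(32, 68), make_standard_prior, domain = dom)
  obs <- deterministic_observer()
  n_on <- run_test(eye, g, observer = obs, priors = on_peak, seed = 5)$n_presentations
  n_off <- run_test(eye, g, observer = obs, priors = off_peak, seed = 5)$n_presentations
  expect_lte(n_on, n_off)
})

test_that("structural priors speed up testing on a glaucomatous eye", {
  g <- the_grid
  eye <- gen_glaucoma_eye(g, "advanced", seed = 88)
  obs <- observer_preset("reliable")
  cfg_z <- strategy_config("standard")
  cfg_s <- strategy_config("structural")
  nz <- ns <- numeric(20)
  for (k in 1:20) {
    nz[k] <- run_test(eye, g, cfg = cfg_z, observer = obs, seed = 1000 + k)$n_presentations
    ns[k] <- run_test(eye, g, cfg = cfg_s, observer = obs, seed = 2000 + k)$n_presentations
  }
  expect_lt(mean(ns), mean(nz))
})

test_that("structural mode requires a GCL map and results export cleanly", {
  g <- the_grid
  eye <- eye_profile(rep(25, 68), cohort = "healthy")  # no map
  expect_error(run_test(eye, g, cfg = strategy_config("structural")), "GCL")
  eye2 <- gen_healthy_eye(g, seed = 9)
  res <- run_test(eye2, g, seed = 9)
  stem <- file.path(withr::local_tempdir(), "t")
  write_test_result(res, stem)
  back <- utils::read.csv(paste0(stem, "_locations.csv"))
  expect_equal(back$estimate, unname(res$estimates), tolerance = 1e-9)
  expect_equal(nrow(utils::read.csv(paste0(stem, "_trace.csv"))),
               res$n_presentations)
})
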