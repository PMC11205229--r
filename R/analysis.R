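#' Mean absolute error of an examination
#'
#' Mean over locations of `|estimate - truth|`, the summary statistic
#' used for simulation accuracy.
#'
#' @param estimates Estimated thresholds, dB (or a `test_result`).
#' @param truth True thresholds, dB, same length.
#' @return MAE, dB.
#' @export
mae <- function(estimates, truth) {
  if (inherits(estimates, "test_result")) estimates <- estimates$estimates
  if (length(estimates) != length(truth)) stop("length mismatch")
  mean(abs(estimates - truth))
}

#' Sample quantiles (type 7)
#'
#' Linear interpolation between order statistics, the convention used
#' for the 2.5%/97.5% simulation summary bars.
#'
#' @param values Nonempty numeric vector.
#' @param probs Probabilities (default `c(0.025, 0.975)`).
#' @return Named quantile vector.
#' @export
summarize_quantiles <- function(values, probs = c(0.025, 0.975)) {
  if (length(values) == 0) stop("empty input")
  stats::quantile(values, probs = probs, type = 7, names = TRUE)
}

#' Condition table for [run_experiment()]
#'
#' @param strategy Character vector over `"zest"`, `"szest"`.
#' @param spatial Logical vector, recycled against `strategy`.
#' @return Data frame of conditions.
#' @export
experiment_conditions <- function(strategy = c("zest", "zest", "szest", "szest"),
                                  spatial = c(FALSE, TRUE, FALSE, TRUE)) {
  stopifnot(all(strategy %in% c("zest", "szest")))
  data.frame(strategy = strategy, spatial = as.logical(spatial))
}

#' Run a simulation experiment
#'
#' Crosses the cohort with the requested strategy/spatial conditions and
#' an observer, repeating each examination `reps_per_eye` times.
#' Per-run seeds are derived from `base_seed` by a counter, so the whole
#' experiment is reproducible and individual runs can be replayed.
#'
#' @param cohort A `cohort` from [gen_cohort()].
#' @param grid A `vf_grid`.
#' @param conditions From [experiment_conditions()].
#' @param observer An [observer_params()].
#' @param reps_per_eye Repetitions per eye per condition (the emulated
#'   design uses 500; scale down for quick runs).
#' @param base_seed Integer master seed.
#' @param normative Normative map for prior construction.
#' @param sf An [sf_params()] for structural priors.
#' @param cfg_overrides Named list of [strategy_config()] arguments
#'   applied to every condition (e.g. `term_sd`).
#' @return List with `results` (one row per eye x rep x condition:
#'   `id`, `cohort`, `severity`, `strategy`, `spatial`, `rep`, `mae`,
#'   `n_presentations`, `n_capped`, `seed`) and `summary` from
#'   [summarize_experiment()].
#' @export
run_experiment <- function(cohort, grid, conditions = experiment_conditions(),
                           observer = observer_preset("reliable"),
                           reps_per_eye = 500, base_seed = 1,
                           normative = make_normative_map(grid),
                           sf = sf_params(), cfg_overrides = list()) {
  stopifnot(inherits(cohort, "cohort"), nrow(conditions) >= 1,
            reps_per_eye >= 1)
  eyes <- cohort$eyes
  n_runs <- length(eyes) * nrow(conditions) * reps_per_eye
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_runs)

  # cache per-eye structural predictions and graphs: they depend only on
  # the eye, not the repetition
  cfg_of <- function(strategy, spatial) {
    args <- c(list(mode = if (strategy == "zest") "standard" else "structural",
                   spatial = spatial), cfg_overrides)
    do.call(strategy_config, args)
  }
  std_priors <- lapply(normative, make_standard_prior)
  std_graph <- build_neighbor_graph(grid, "standard")

  rows <- vector("list", n_runs)
  run <- 0L
  for (e in seq_along(eyes)) {
    eye <- eyes[[e]]
    str_priors <- NULL; str_graph <- NULL
    if (any(conditions$strategy == "szest")) {
      gs <- sample_gcl(eye$gcl_map, grid)
      pred <- predict_sensitivity(gs$mean_thickness, sf)
      w_ab <- predict_abnormal_weight(pred, normative, sf)
      str_priors <- mapply(make_structural_prior, pred, w_ab, SIMPLIFY = FALSE)
      str_graph <- build_neighbor_graph(grid, "structural", predictions = pred)
    }
    for (ci in seq_len(nrow(conditions))) {
      strategy <- conditions$strategy[ci]
      spatial <- conditions$spatial[ci]
      cfg <- cfg_of(strategy, spatial)
      priors <- if (strategy == "zest") std_priors else str_priors
      graph <- if (strategy == "zest") std_graph else str_graph
      for (r in seq_len(reps_per_eye)) {
        run <- run + 1L
        res <- run_test(eye, grid, cfg = cfg, observer = observer,
                        normative = normative, sf = sf, priors = priors,
                        graph = graph, seed = seeds[run])
        rows[[run]] <- data.frame(
          id = eye$id, cohort = eye$cohort, severity = eye$severity,
          strategy = strategy, spatial = spatial, rep = r,
          mae = mae(res, eye$true_thresholds),
          n_presentations = res$n_presentations,
          n_capped = sum(res$per_location$capped),
          seed = seeds[run]
        )
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, summary = summarize_experiment(results))
}

#' Summarize an experiment table
#'
#' Per (cohort, strategy, spatial) cell: mean and 2.5%/97.5% quantiles
#' of the MAE and presentation-count distributions, plus the capped-
#' location total.
#'
#' @param results The `results` data frame from [run_experiment()].
#' @return Data frame, one row per cell.
#' @export
summarize_experiment <- function(results) {
  cells <- unique(results[c("cohort", "strategy", "spatial")])
  out <- lapply(seq_len(nrow(cells)), function(k) {
    m <- results$cohort == cells$cohort[k] &
      results$strategy == cells$strategy[k] &
      results$spatial == cells$spatial[k]
    qm <- summarize_quantiles(results$mae[m])
    qn <- summarize_quantiles(results$n_presentations[m])
    data.frame(
      cohort = cells$cohort[k], strategy = cells$strategy[k],
      spatial = cells$spatial[k], n_runs = sum(m),
      mae_mean = mean(results$mae[m]), mae_q025 = qm[[1]], mae_q975 = qm[[2]],
      pres_mean = mean(results$n_presentations[m]),
      pres_q025 = qn[[1]], pres_q975 = qn[[2]],
      capped_total = sum(results$n_capped[m])
    )
  })
  res <- do.call(rbind, out)
  res[order(res$cohort, res$strategy, res$spatial), ]
}

#' Bland-Altman test-retest / agreement analysis
#'
#' Point-wise differences `d = test1 - test2`: bias = mean(d), 95%
#' limits = bias +/- 1.96 sd(d), and the bias equation (least squares of
#' d on the pairwise mean). Confidence intervals for the bias and each
#' limit are computed by a percentile bootstrap resampling *subjects*
#' (clusters of locations) with replacement.
#'
#' @param test1,test2 Paired per-location sensitivities, dB.
#' @param subject Subject id per location (required when `n_boot > 0`;
#'   at least 2 distinct subjects).
#' @param n_boot Bootstrap resamples (default 1000; 0 skips CIs).
#' @param conf CI level (default 0.95).
#' @return A `bland_altman` list: `bias`, `lor_lo`, `lor_hi`,
#'   `bias_intercept`, `bias_slope`, `n`, and (with bootstrap) `ci`, a
#'   3x2 matrix of percentile CIs for bias and both limits.
#' @export
bland_altman <- function(test1, test2, subject = NULL, n_boot = 1000,
                         conf = 0.95) {
  stopifnot(length(test1) == length(test2))
  d <- test1 - test2
  avg <- (test1 + test2) / 2
  point <- function(d, avg) {
    bias <- mean(d)
    s <- stats::sd(d)
    co <- if (stats::var(avg) > 0) {
      stats::lm.fit(cbind(1, avg), d)$coefficients
    } else {
      c(bias, 0)
    }
    c(bias = bias, lor_lo = bias - 1.96 * s, lor_hi = bias + 1.96 * s,
      bias_intercept = co[[1]], bias_slope = co[[2]])
  }
  est <- point(d, avg)
  ci <- NULL
  if (n_boot > 0) {
    if (is.null(subject)) stop("subject ids are required for the bootstrap")
    ids <- unique(subject)
    if (length(ids) < 2) stop("need at least 2 subjects for the bootstrap")
    by_subj <- split(seq_along(d), subject)
    boots <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("bias", "lor_lo", "lor_hi")))
    for (b in seq_len(n_boot)) {
      take <- unlist(by_subj[sample.int(length(ids), replace = TRUE)],
                     use.names = FALSE)
      p <- point(d[take], avg[take])
      boots[b, ] <- p[1:3]
    }
    a <- (1 - conf) / 2
    ci <- t(apply(boots, 2, stats::quantile, probs = c(a, 1 - a)))
  }
  structure(c(as.list(est), list(n = length(d), ci = ci, conf = conf)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.3f dB, 95%% limits [%.3f, %.3f] dB\n",
    x$n, x$bias, x$lor_lo, x$lor_hi
  ))
  cat(sprintf("bias equation: d = %.3f + %.3f * mean\n",
              x$bias_intercept, x$bias_slope))
  if (!is.null(x$ci)) {
    cat(sprintf("%.0f%% bootstrap CIs: bias [%.3f, %.3f], lower limit [%.3f, %.3f], upper limit [%.3f, %.3f]\n",
                100 * x$conf, x$ci["bias", 1], x$ci["bias", 2],
                x$ci["lor_lo", 1], x$ci["lor_lo", 2],
                x$ci["lor_hi", 1], x$ci["lor_hi", 2]))
  }
  invisible(x)
}
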