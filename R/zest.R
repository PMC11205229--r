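#' Strategy configuration
#'
#' All tunables of the adaptive testing loop. Defaults follow the
#' canonical procedure: likelihood is the cdf of a Gaussian with 1-dB SD
#' and asymptotes at 0.03 and 0.97 centered on the presented intensity;
#' the next stimulus is the posterior mean; a location terminates when
#' its posterior SD falls to 1.5 dB or below.
#'
#' @param mode `"standard"` (ZEST, population priors) or `"structural"`
#'   (S-ZEST, priors individualized from GCL thickness).
#' @param spatial Propagate down-weighted likelihood updates to
#'   neighboring locations?
#' @param likelihood_sd SD of the likelihood cdf, dB.
#' @param asymptote_lo,asymptote_hi Lower/upper likelihood asymptotes.
#' @param term_sd Termination bound on the posterior SD, dB.
#' @param max_presentations Per-location presentation cap (safety
#'   against pathological response sequences); cap hits are flagged.
#' @param stimulus_rounding Stimulus quantization, dB (round-half-even).
#' @param presentation_time_s Per-presentation time constant used only
#'   for the reported duration model, seconds.
#' @return A `strategy_config` object.
#' @export
strategy_config <- function(mode = c("standard", "structural"),
                            spatial = FALSE, likelihood_sd = 1,
                            asymptote_lo = 0.03, asymptote_hi = 0.97,
                            term_sd = 1.5, max_presentations = 15,
                            stimulus_rounding = 1,
                            presentation_time_s = 1.6) {
  mode <- match.arg(mode)
  stopifnot(asymptote_lo > 0, asymptote_hi < 1, asymptote_lo < asymptote_hi,
            likelihood_sd > 0, term_sd > 0, max_presentations >= 1,
            stimulus_rounding > 0)
  structure(list(mode = mode, spatial = isTRUE(spatial),
                 likelihood_sd = likelihood_sd,
                 asymptote_lo = asymptote_lo, asymptote_hi = asymptote_hi,
                 term_sd = term_sd, max_presentations = max_presentations,
                 stimulus_rounding = stimulus_rounding,
                 presentation_time_s = presentation_time_s),
            class = "strategy_config")
}

#' Likelihood of a "seen" response across candidate thresholds
#'
#' For each candidate threshold `t`,
#' `L(t) = lo + (hi - lo) * Phi((t - presented) / likelihood_sd)`:
#' strictly increasing in `t`, approaching `asymptote_lo` far below the
#' presented intensity and `asymptote_hi` far above it. The "not seen"
#' likelihood is `1 - L`.
#'
#' @param presented Presented intensity, dB.
#' @param domain Candidate thresholds, from [zest_domain()].
#' @param cfg A [strategy_config()].
#' @return Numeric vector over `domain`.
#' @export
likelihood_seen <- function(presented, domain = zest_domain(),
                            cfg = strategy_config()) {
  stopifnot(is.finite(presented))
  cfg$asymptote_lo + (cfg$asymptote_hi - cfg$asymptote_lo) *
    stats::pnorm((domain - presented) / cfg$likelihood_sd)
}

#' Bayesian update of a location's belief
#'
#' Posterior mass proportional to prior times the response-appropriate
#' likelihood, renormalized. Because the asymptotes are strictly inside
#' (0, 1), the posterior can never collapse to zero mass.
#'
#' @param pdf A [discrete_pdf()] (its domain is used).
#' @param presented Presented intensity, dB.
#' @param response `TRUE` for "seen".
#' @param cfg A [strategy_config()].
#' @return Updated [discrete_pdf()].
#' @export
update_pdf <- function(pdf, presented, response, cfg = strategy_config()) {
  check_pdf(pdf)
  L <- likelihood_seen(presented, pdf$domain, cfg)
  if (!response) L <- 1 - L
  post <- pdf$mass * L
  if (sum(post) <= 0) stop("posterior has zero mass")  # unreachable with asymptotes in (0,1)
  discrete_pdf(pdf$domain, post)
}

#' Spatially enhanced update
#'
#' Applies the full likelihood update to the tested location and a
#' flattened likelihood `L_w = (1 - w) + w * L` (with `L` the
#' response-appropriate likelihood and `w` the edge weight) to each
#' connected, unterminated neighbor. At `w = 0` the neighbor is
#' untouched; at `w = 1` it receives the full update. Terminated
#' neighbors and unconnected locations are unchanged.
#'
#' @param states List of location states, each a list with elements
#'   `pdf` ([discrete_pdf()]) and `terminated` (logical).
#' @param graph A `neighbor_graph` from [build_neighbor_graph()].
#' @param tested_index Index of the tested location.
#' @param presented Presented intensity, dB.
#' @param response `TRUE` for "seen".
#' @param cfg A [strategy_config()].
#' @return The updated list of states.
#' @export
spatial_update <- function(states, graph, tested_index, presented, response,
                           cfg = strategy_config()) {
  stopifnot(tested_index >= 1, tested_index <= length(states))
  st <- states[[tested_index]]
  st$pdf <- update_pdf(st$pdf, presented, response, cfg)
  states[[tested_index]] <- st
  nbs <- c(graph$j[graph$i == tested_index], graph$i[graph$j == tested_index])
  ws <- c(graph$weight[graph$i == tested_index],
          graph$weight[graph$j == tested_index])
  for (k in seq_along(nbs)) {
    nb <- states[[nbs[k]]]
    if (isTRUE(nb$terminated)) next
    L <- likelihood_seen(presented, nb$pdf$domain, cfg)
    if (!response) L <- 1 - L
    Lw <- (1 - ws[k]) + ws[k] * L
    nb$pdf <- discrete_pdf(nb$pdf$domain, nb$pdf$mass * Lw)
    states[[nbs[k]]] <- nb
  }
  states
}

#' Select the next stimulus for a location
#'
#' The posterior mean, rounded to the stimulus quantum (round-half-even)
#' and clipped to the domain range.
#'
#' @param pdf A [discrete_pdf()].
#' @param cfg A [strategy_config()].
#' @return Intensity, dB.
#' @export
select_stimulus <- function(pdf, cfg = strategy_config()) {
  m <- pdf_mean(pdf)
  q <- cfg$stimulus_rounding
  s <- round(m / q) * q
  min(max(s, min(pdf$domain)), max(pdf$domain))
}

#' Termination criterion
#'
#' A location has converged when the SD of its posterior is at or below
#' `term_sd` (boundary inclusive).
#'
#' @param pdf A [discrete_pdf()].
#' @param cfg A [strategy_config()].
#' @return Logical.
#' @export
is_terminated <- function(pdf, cfg = strategy_config()) {
  pdf_sd(pdf) <= cfg$term_sd
}

#' Run one simulated examination
#'
#' The full adaptive loop over all 68 locations: per-location priors are
#' built from the normative map (standard mode) or from the eye's GCL
#' thickness map through the structure-function model (structural mode);
#' at each step an unterminated location is chosen uniformly at random,
#' the posterior-mean stimulus is presented to the simulated observer,
#' and the response updates the location (and, with spatial enhancement,
#' its graph neighbors with down-weighted likelihoods) until every
#' location has terminated or hit the presentation cap. Estimates are
#' final posterior means.
#'
#' @param eye An [eye_profile()] (structural mode requires its
#'   `gcl_map`).
#' @param grid A `vf_grid` (displaced coordinates are used for GCL
#'   sampling).
#' @param cfg A [strategy_config()].
#' @param observer An [observer_params()].
#' @param normative Numeric vector of 68 normative sensitivities, dB
#'   (see [make_normative_map()]).
#' @param sf An [sf_params()], structural mode only.
#' @param priors Optional list of 68 [discrete_pdf()]s overriding the
#'   built-in prior construction.
#' @param graph Optional `neighbor_graph` override (otherwise built per
#'   mode when `cfg$spatial`).
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param domain From [zest_domain()].
#' @return A `test_result`: list with `estimates` (68 dB values),
#'   `n_presentations` (total), `per_location` (data frame: `index`,
#'   `estimate`, `final_sd`, `n_presentations`, `terminated`, `capped`),
#'   `trace` (data frame: `step`, `location`, `stimulus`, `response`),
#'   `duration_model_s`, `seed`, and the strategy labels.
#' @export
run_test <- function(eye, grid, cfg = strategy_config(),
                     observer = observer_preset("reliable"),
                     normative = make_normative_map(grid),
                     sf = sf_params(), priors = NULL, graph = NULL,
                     seed = NULL, domain = zest_domain()) {
  stopifnot(inherits(eye, "eye_profile"), inherits(grid, "vf_grid"))
  n <- nrow(grid)
  if (!is.null(seed)) set.seed(seed)

  predictions <- NULL
  if (is.null(priors)) {
    if (cfg$mode == "standard") {
      priors <- lapply(normative, make_standard_prior, domain = domain)
    } else {
      if (is.null(eye$gcl_map)) {
        stop("structural mode requires an eye with a GCL thickness map")
      }
      gs <- sample_gcl(eye$gcl_map, grid)
      predictions <- predict_sensitivity(gs$mean_thickness, sf)
      w_ab <- predict_abnormal_weight(predictions, normative, sf)
      priors <- mapply(make_structural_prior, predictions, w_ab,
                       MoreArgs = list(domain = domain), SIMPLIFY = FALSE)
    }
  }
  stopifnot(length(priors) == n)

  nb <- NULL
  wt <- 0
  if (cfg$spatial) {
    if (is.null(graph)) {
      graph <- if (cfg$mode == "standard") {
        build_neighbor_graph(grid, "standard")
      } else {
        if (is.null(predictions)) {
          gs <- sample_gcl(eye$gcl_map, grid)
          predictions <- predict_sensitivity(gs$mean_thickness, sf)
        }
        build_neighbor_graph(grid, "structural", predictions = predictions)
      }
    }
    nb <- neighbor_list(graph)
    wt <- graph$weight[1]
    if (nrow(graph) == 0) nb <- NULL
  }

  # dense state for speed: one mass column per location
  P <- vapply(priors, function(p) p$mass, numeric(length(domain)))
  truth <- eye$true_thresholds
  lo <- cfg$asymptote_lo; span <- cfg$asymptote_hi - cfg$asymptote_lo
  lsd <- cfg$likelihood_sd
  counts <- integer(n)
  capped <- logical(n)
  terminated <- vapply(seq_len(n), function(k) {
    m <- sum(domain * P[, k])
    sqrt(max(0, sum(domain^2 * P[, k]) - m^2)) <= cfg$term_sd
  }, logical(1))

  cap_total <- n * cfg$max_presentations
  tr_loc <- integer(cap_total); tr_stim <- numeric(cap_total)
  tr_resp <- logical(cap_total)
  step <- 0L
  dmin <- min(domain); dmax <- max(domain); q <- cfg$stimulus_rounding

  while (any(!terminated)) {
    active <- which(!terminated)
    idx <- if (length(active) == 1L) active else active[sample.int(length(active), 1L)]
    p <- P[, idx]
    m <- sum(domain * p)
    stim <- min(max(round(m / q) * q, dmin), dmax)
    resp <- stats::runif(1) < prob_seen(truth[idx], stim, observer)
    L <- lo + span * stats::pnorm((domain - stim) / lsd)
    if (!resp) L <- 1 - L
    p <- p * L
    p <- p / sum(p)
    P[, idx] <- p
    counts[idx] <- counts[idx] + 1L
    step <- step + 1L
    tr_loc[step] <- idx; tr_stim[step] <- stim; tr_resp[step] <- resp

    m <- sum(domain * p)
    if (sqrt(max(0, sum(domain^2 * p) - m^2)) <= cfg$term_sd) {
      terminated[idx] <- TRUE
    } else if (counts[idx] >= cfg$max_presentations) {
      terminated[idx] <- TRUE
      capped[idx] <- TRUE
    }

    if (!is.null(nb)) {
      for (k in nb[[idx]]) {
        if (terminated[k]) next
        Lw <- (1 - wt) + wt * L
        pk <- P[, k] * Lw
        pk <- pk / sum(pk)
        P[, k] <- pk
        mk <- sum(domain * pk)
        if (sqrt(max(0, sum(domain^2 * pk) - mk^2)) <= cfg$term_sd) {
          terminated[k] <- TRUE
        }
      }
    }
  }

  means <- colSums(P * domain)
  sds <- sqrt(pmax(0, colSums(P * domain^2) - means^2))
  per_loc <- data.frame(
    index = grid$index, estimate = means, final_sd = sds,
    n_presentations = counts, terminated = !capped, capped = capped
  )
  structure(
    list(estimates = means, n_presentations = sum(counts),
         per_location = per_loc,
         trace = data.frame(step = seq_len(step), location = tr_loc[seq_len(step)],
                            stimulus = tr_stim[seq_len(step)],
                            response = tr_resp[seq_len(step)]),
         duration_model_s = sum(counts) * cfg$presentation_time_s,
         seed = seed, mode = cfg$mode, spatial = cfg$spatial),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf(
    "%s%s examination: %d presentations (%.1f s modeled), %d/%d locations capped\n",
    if (x$mode == "standard") "ZEST" else "S-ZEST",
    if (x$spatial) " + spatial" else "",
    x$n_presentations, x$duration_model_s,
    sum(x$per_location$capped), nrow(x$per_location)
  ))
  invisible(x)
}

#' Export a test result as delimited text
#'
#' Writes `<stem>_locations.csv` (per-location estimate, final posterior
#' SD, count, termination flags) and `<stem>_trace.csv` (presentation
#' sequence).
#'
#' @param result A `test_result`.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_test_result <- function(result, stem) {
  f1 <- paste0(stem, "_locations.csv")
  f2 <- paste0(stem, "_trace.csv")
  utils::write.csv(result$per_location, f1, row.names = FALSE)
  utils::write.csv(result$trace, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
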