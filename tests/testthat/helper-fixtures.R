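# shared fixtures, built in code (no stored data)

the_grid <- displace_locations(build_10_2_grid())

# deterministic observer: no false responses, step psychometric function
deterministic_observer <- function() {
  observer_params(fp = 0, fn = 0, slope_cap = 1e-6)
}

# tiny 5-bin domain used by the engine oracle
domain5 <- c(0, 10, 20, 30, 40)

# explicit Bayes step, written independently of update_pdf: plain
# arithmetic on the mass vector
oracle_bayes_step <- function(mass, domain, stim, seen,
                              lo = 0.03, hi = 0.97, lsd = 1) {
  L <- lo + (hi - lo) * pnorm((domain - stim) / lsd)
  if (!seen) L <- 1 - L
  w <- mass * L
  w / sum(w)
}

oracle_mean <- function(mass, domain) sum(mass * domain)
oracle_sd <- function(mass, domain) {
  m <- sum(mass * domain)
  sqrt(sum(mass * domain^2) - m^2)
}
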