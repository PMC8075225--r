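# Closed-form oracles for special exponent pairs, kept independent of the
# package's numerical integration path.

# logistic growth BP(1, 2): m(t) = m_max / (1 + (m_max/c - 1) exp(-p t))
logistic_closed <- function(t, c, p, q) {
  m_max <- p / q
  m_max / (1 + (m_max / c - 1) * exp(-p * t))
}

# Brody / monomolecular BP(0, 1): m(t) = p/q - (p/q - c) exp(-q t)
brody_closed <- function(t, c, p, q) {
  p / q - (p / q - c) * exp(-q * t)
}

# a realistic noiseless blue-tit-like logistic trajectory on the study grid
make_logistic_series <- function(c = 1.1, p = 0.5, m_max = 11,
                                 times = seq(0, 14, by = 2), sigma = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- logistic_closed(times, c, p, p / m_max)
  mass_series(times, mu * exp(stats::rnorm(length(mu), 0, sigma)))
}

# light annealing configuration for unit tests (coarse problems, warm starts)
test_config <- function(...) {
  bp_anneal_config(iters = 200, restarts = 1, polish = 120, ...)
}
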