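# shared fixture builders; everything is generated in code

canonical_f <- c(SpT = 40, pSpT = 8, pST = 20, ST = 38)

osc_default <- function(period = 24.7) oscillation_model(period = period)

# oscillating abundances over 4 days at 0.5 h sampling
osc_abund <- function(period = 24.7, span = 96, dt = 0.5) {
  generate_oscillation_abundances(osc_default(period), seq(0, span, by = dt))
}

# unit-height Gaussian spectrum on a 1 nm grid
gaussian_spectrum <- function(mu = 340, sigma = 15, grid = seq(300, 400, 1),
                              amplitude = 1) {
  emission_spectrum(grid, amplitude * exp(-(grid - mu)^2 / (2 * sigma^2)))
}

# analytic integral of a Gaussian band over [lo, hi]
gaussian_band_integral <- function(mu, sigma, lo, hi, amplitude = 1) {
  amplitude * sigma * sqrt(2 * pi) *
    (pnorm((hi - mu) / sigma) - pnorm((lo - mu) / sigma))
}

# random simplex trajectory from random oscillation configs
random_osc_model <- function() {
  period <- runif(1, 18, 30)
  oscillation_model(
    period = period,
    state_phases = sort(runif(4, 0, period)),
    state_widths = runif(4, period / 12, period / 5),
    state_floors = runif(4, 0.01, 0.1))
}

# noise draw under a local seed, leaving the global RNG untouched
with_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n, 0, sd)
}
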