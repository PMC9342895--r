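#' Per-phosphostate emission band model
#'
#' Each phosphostate contributes a skew-normal emission band in wavelength:
#' amplitude x exp(-z^2/2) x 2 Phi(skew z), z = (lambda - lambda_max)/width.
#' Skew 0 recovers a plain Gaussian (real Trp emission is red-tailed, so a
#' positive skew is the realistic default). A mixture spectrum is the
#' abundance-weighted sum of the four bands plus a constant background offset
#' (attributed to KaiA fluorescence in reconstituted reactions) plus i.i.d.
#' Gaussian noise per wavelength.
#'
#' Default band centres differ by a few nm and default amplitudes follow the
#' strongly state-dependent intensities seen for the engineered W419 probe
#' (quenched in pSpT, bright in SpT/ST).
#'
#' @param band_lambda_max named numeric, nominal band centre per state (nm);
#'   must lie on the wavelength grid range.
#' @param band_amplitude named numeric, non-negative peak amplitude per state
#'   (normalized F units).
#' @param band_width named numeric, band width parameter per state (nm).
#' @param band_skew named numeric, skewness per state (0 = Gaussian).
#' @param wavelength_grid wavelengths (nm), strictly increasing.
#' @param noise_sigma additive noise SD per wavelength (>= 0).
#' @param offset constant background (normalized F units).
#' @param rng_seed integer seed used when noise is drawn.
#' @return object of class `spectral_state_model`.
#' @export
spectral_state_model <- function(band_lambda_max = c(SpT = 338, pSpT = 334,
                                                     pST = 336, ST = 337),
                                 band_amplitude = c(SpT = 40, pSpT = 8,
                                                    pST = 20, ST = 38),
                                 band_width = rep(22, 4),
                                 band_skew = rep(1.5, 4),
                                 wavelength_grid = seq(300, 400, by = 1),
                                 noise_sigma = 0,
                                 offset = 0,
                                 rng_seed = 1L) {
  band_lambda_max <- as_state_vector(band_lambda_max, "band_lambda_max")
  band_amplitude <- as_state_vector(band_amplitude, "band_amplitude")
  band_width <- as_state_vector(band_width, "band_width")
  band_skew <- as_state_vector(band_skew, "band_skew")
  if (any(diff(wavelength_grid) <= 0)) {
    stop_kf("validation", "wavelength_grid must be strictly increasing")
  }
  if (any(band_lambda_max < min(wavelength_grid) |
          band_lambda_max > max(wavelength_grid))) {
    stop_kf("validation", "band_lambda_max must lie within the wavelength grid")
  }
  if (any(band_amplitude < 0)) {
    stop_kf("validation", "band amplitudes must be non-negative")
  }
  if (any(band_width <= 0)) stop_kf("validation", "band widths must be positive")
  if (noise_sigma < 0) stop_kf("validation", "noise_sigma must be >= 0")
  structure(list(band_lambda_max = band_lambda_max,
                 band_amplitude = band_amplitude,
                 band_width = band_width, band_skew = band_skew,
                 wavelength_grid = wavelength_grid,
                 noise_sigma = noise_sigma, offset = offset,
                 rng_seed = as.integer(rng_seed)),
            class = "spectral_state_model")
}

# skew-normal shaped band with unit peak at skew = 0
state_band <- function(lambda, center, amplitude, width, skew) {
  z <- (lambda - center) / width
  amplitude * exp(-z^2 / 2) * 2 * pnorm(skew * z)
}

#' Synthesize an emission spectrum from a phosphostate mixture
#'
#' @param spec_model a [spectral_state_model()].
#' @param abundances 4-vector on the simplex (tolerance 1e-6), named or in
#'   canonical order.
#' @param rng_seed optional override of the model's seed for the noise draw.
#' @return an [emission_spectrum()] on the model's wavelength grid.
#' @examples
#' sm <- spectral_state_model(noise_sigma = 0)
#' s <- synthesize_spectrum(sm, c(SpT = 1, pSpT = 0, pST = 0, ST = 0))
#' find_lambda_max(s)
#' @export
synthesize_spectrum <- function(spec_model, abundances, rng_seed = NULL) {
  stopifnot(inherits(spec_model, "spectral_state_model"))
  abundances <- as_state_vector(abundances, "abundances")
  check_simplex(abundances, tol = 1e-6, what = "abundances")
  lambda <- spec_model$wavelength_grid
  y <- rep(spec_model$offset, length(lambda))
  for (s in KAIC_STATES) {
    y <- y + abundances[[s]] *
      state_band(lambda, spec_model$band_lambda_max[[s]],
                 spec_model$band_amplitude[[s]],
                 spec_model$band_width[[s]], spec_model$band_skew[[s]])
  }
  if (spec_model$noise_sigma > 0) {
    seed <- rng_seed %||% spec_model$rng_seed
    y <- y + with_local_seed(seed, rnorm(length(lambda), 0, spec_model$noise_sigma))
  }
  emission_spectrum(lambda, y,
                    meta = list(source = "synthetic",
                                abundances = abundances,
                                offset = spec_model$offset,
                                noise_sigma = spec_model$noise_sigma))
}

# evaluate expr under a local RNG seed without disturbing the global stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
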