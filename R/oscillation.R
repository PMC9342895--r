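#' Phenomenological model of circadian phosphostate oscillation
#'
#' Generates smooth, exactly periodic, simplex-valued abundance waveforms:
#' each state carries a wrapped-Gaussian pulse centred on its peak phase,
#' sitting on a baseline floor, and the four weights are renormalized to sum
#' to one at every time point. With the default phases the peak order over a
#' cycle follows the canonical progression ST -> SpT -> pSpT -> pST.
#'
#' This is a waveform model, not a mechanistic KaiABC oscillator: it
#' reproduces the phase-ordered, partially overlapping abundance peaks seen
#' on phosphorylation gels without modelling KaiA/KaiB binding.
#'
#' @param period oscillation period in hours (> 0).
#' @param state_phases named numeric, peak time of each state within the
#'   cycle (h). Defaults place ST, SpT, pSpT, pST peaks a quarter period
#'   apart in cycle order.
#' @param state_widths named numeric, Gaussian pulse SD per state (h, > 0).
#' @param state_floors named numeric, non-negative baseline weight per state
#'   (a state never fully vanishes on a gel).
#' @return object of class `oscillation_model`.
#' @examples
#' m <- oscillation_model(period = 24.7)
#' a <- generate_oscillation_abundances(m, times = seq(0, 96, by = 0.5))
#' range(rowSums(abundance_matrix(a)))
#' @export
oscillation_model <- function(period = 24.7,
                              state_phases = c(ST = 0, SpT = 1, pSpT = 2,
                                               pST = 3) * period / 4,
                              state_widths = rep(period / 8, 4),
                              state_floors = rep(0.05, 4)) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    stop_kf("validation", "period must be a positive scalar (h)")
  }
  state_phases <- as_state_vector(state_phases, "state_phases")
  state_widths <- as_state_vector(state_widths, "state_widths")
  state_floors <- as_state_vector(state_floors, "state_floors")
  if (any(state_widths <= 0)) {
    stop_kf("validation", "state_widths must be positive")
  }
  if (any(state_floors < 0)) {
    stop_kf("validation", "state_floors must be non-negative")
  }
  structure(list(period = period, state_phases = state_phases,
                 state_widths = state_widths, state_floors = state_floors),
            class = "oscillation_model")
}

# wrapped Gaussian pulse: exactly periodic in t with period P
wrapped_gaussian <- function(t, phase, width, period, n_images = 5L) {
  d <- ((t - phase + period / 2) %% period) - period / 2
  out <- 0
  for (k in -n_images:n_images) {
    out <- out + exp(-(d + k * period)^2 / (2 * width^2))
  }
  out
}

#' Generate periodic simplex-valued abundance trajectories
#'
#' @param model an [oscillation_model()].
#' @param times strictly increasing sampling times (h); must span at least
#'   one full period.
#' @return an `abundance_timecourse` whose rows sum to 1 exactly (by
#'   renormalization) and which satisfies A(t + period) = A(t).
#' @export
generate_oscillation_abundances <- function(model, times) {
  stopifnot(inherits(model, "oscillation_model"))
  check_times(times)
  if (diff(range(times)) < model$period) {
    stop_kf("validation",
            "times must cover at least one full period (%.3g h)", model$period)
  }
  W <- vapply(KAIC_STATES, function(s) {
    model$state_floors[[s]] +
      wrapped_gaussian(times, model$state_phases[[s]],
                       model$state_widths[[s]], model$period)
  }, numeric(length(times)))
  W <- matrix(W, nrow = length(times))
  new_abundance_timecourse(times, W / rowSums(W))
}

#' @export
print.oscillation_model <- function(x, ...) {
  cat(sprintf("Oscillation model: period %.3g h\n", x$period))
  cat("  peak phases (h):",
      paste(sprintf("%s %.2f", KAIC_STATES, x$state_phases), collapse = ", "),
      "\n")
  invisible(x)
}
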