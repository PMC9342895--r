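#' Per-state fluorescence intensities
#'
#' Container for the coefficients of the linear unmixing model
#' F_app(t) = sum_i F_i A_i(t) + offset: one intrinsic intensity per
#' phosphostate plus an optional constant background, with standard errors
#' and fit diagnostics when produced by [fit_state_fluorescence()].
#'
#' @param f_values named numeric, intensity per state (normalized F units).
#' @param offset constant background term (normalized F units).
#' @param f_se,offset_se standard errors (NA when not estimated).
#' @param construct,condition sample labels (e.g. "WT" / "F419W",
#'   "KaiC-alone" / "KaiA+KaiB+KaiC").
#' @param sigma residual SD of the generating fit, if any.
#' @param kappa condition number of the design matrix, if any.
#' @return object of class `state_fluorescence`.
#' @export
state_fluorescence <- function(f_values, offset = 0,
                               f_se = rep(NA_real_, 4), offset_se = NA_real_,
                               construct = "synthetic", condition = NA_character_,
                               sigma = NA_real_, kappa = NA_real_) {
  f_values <- as_state_vector(f_values, "f_values")
  f_se <- as_state_vector(f_se, "f_se")
  if (any(!is.na(f_se) & f_se < 0)) {
    stop_kf("validation", "standard errors must be non-negative")
  }
  structure(list(f_values = f_values, f_se = f_se,
                 offset = offset, offset_se = offset_se,
                 construct = construct, condition = condition,
                 sigma = sigma, kappa = kappa),
            class = "state_fluorescence")
}

#' @export
print.state_fluorescence <- function(x, ...) {
  cat(sprintf("Per-state fluorescence (%s%s)\n", x$construct,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  for (s in KAIC_STATES) {
    se <- x$f_se[[s]]
    cat(sprintf("  F_%-5s = %8.3f%s\n", s, x$f_values[[s]],
                if (is.na(se)) "" else sprintf(" +/- %.3f", se)))
  }
  cat(sprintf("  offset  = %8.3f%s\n", x$offset,
              if (is.na(x$offset_se)) "" else sprintf(" +/- %.3f", x$offset_se)))
  if (!is.na(x$sigma)) cat(sprintf("  residual SD %.4g, condition number %.3g\n",
                                   x$sigma, x$kappa))
  invisible(x)
}

#' Apparent fluorescence time course
#'
#' @param times times in hours, strictly increasing.
#' @param f_app apparent band-integrated fluorescence (normalized units).
#' @param temperature_c sample temperature (degrees C).
#' @param construct,condition sample labels.
#' @return a `fluor_timecourse` data.frame with columns `time_h`, `f_app`
#'   and metadata attributes.
#' @export
fluor_timecourse <- function(times, f_app, temperature_c = 30,
                             construct = "WT", condition = "KaiA+KaiB+KaiC") {
  check_times(times)
  if (length(f_app) != length(times) || anyNA(f_app) || any(!is.finite(f_app))) {
    stop_kf("validation", "f_app must be finite and match times in length")
  }
  df <- data.frame(time_h = times, f_app = f_app)
  attr(df, "temperature_c") <- temperature_c
  attr(df, "construct") <- construct
  attr(df, "condition") <- condition
  class(df) <- c("fluor_timecourse", "data.frame")
  df
}

#' Compose an apparent-fluorescence trace from states and abundances
#'
#' Forward model: F_app(t) = sum_i F_i A_i(t) + offset + eps(t), with
#' eps i.i.d. Gaussian of SD `noise_sigma` (noiseless when 0). The same
#' linear map, without noise, is exposed as [simulate_fapp()] for comparing
#' fits with observations.
#'
#' @param state_f a [state_fluorescence()] (its `offset` is used).
#' @param abundances an `abundance_timecourse`.
#' @param noise_sigma additive noise SD (normalized F units).
#' @param rng_seed integer seed for the noise draw.
#' @param temperature_c,construct,condition metadata for the output trace.
#' @return a [fluor_timecourse()] on the abundance time grid.
#' @export
compose_fapp <- function(state_f, abundances, noise_sigma = 0, rng_seed = 1L,
                         temperature_c = 30, construct = NULL,
                         condition = "KaiA+KaiB+KaiC") {
  stopifnot(inherits(state_f, "state_fluorescence"),
            inherits(abundances, "abundance_timecourse"))
  if (anyNA(state_f$f_values)) {
    stop_kf("validation", "state_f must provide all four state intensities")
  }
  A <- abundance_matrix(abundances)
  y <- as.numeric(A %*% state_f$f_values) + state_f$offset
  if (noise_sigma > 0) {
    y <- y + with_local_seed(rng_seed, rnorm(length(y), 0, noise_sigma))
  }
  fluor_timecourse(abundances$time_h, y, temperature_c = temperature_c,
                   construct = construct %||% state_f$construct,
                   condition = condition)
}
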