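#' Convert between Q10 and activation energy
#'
#' Q10 is the factor by which the cycle frequency (24/period, cycles per
#' day) accelerates when the temperature rises from `t1_c` to `t2_c`
#' (default 30 to 40 degrees C). Under an Arrhenius law,
#' \deqn{E_a = \frac{R \ln Q_{10}}{1/T_1 - 1/T_2},\qquad
#'       Q_{10} = \exp\!\left[\frac{E_a}{R}\left(\frac{1}{T_1}-\frac{1}{T_2}\right)\right],}
#' with temperatures in kelvin and R = 1.987e-3 kcal/(mol K). A perfectly
#' temperature-compensated clock has Q10 = 1 (E_a = 0); an ordinary
#' chemical reaction with Q10 = 2 corresponds to about 13.1 kcal/mol over
#' 30-40 degrees C.
#'
#' @param q10 Q10 factor (> 0); give exactly one of `q10` or `e_a`.
#' @param e_a activation energy (kcal/mol).
#' @param t1_c,t2_c reference temperatures (degrees C), distinct.
#' @return the other quantity (`e_a` in kcal/mol, or `q10`).
#' @examples
#' q10_ea_convert(q10 = 2)          # ~13.1 kcal/mol
#' q10_ea_convert(e_a = 0)          # Q10 = 1
#' @export
q10_ea_convert <- function(q10 = NULL, e_a = NULL, t1_c = 30, t2_c = 40) {
  if (t1_c == t2_c) stop_kf("validation", "t1_c and t2_c must differ")
  if (is.null(q10) == is.null(e_a)) {
    stop_kf("validation", "give exactly one of q10 or e_a")
  }
  dinv <- 1 / celsius_to_kelvin(t1_c) - 1 / celsius_to_kelvin(t2_c)
  if (!is.null(q10)) {
    if (q10 <= 0) stop_kf("validation", "q10 must be positive")
    R_KCAL * log(q10) / dinv
  } else {
    exp(e_a / R_KCAL * dinv)
  }
}

#' Arrhenius analysis of period versus temperature
#'
#' Regresses the log cycle frequency, ln(24/period), on reciprocal absolute
#' temperature; the slope is -E_a/R. Q10 between the two reference
#' temperatures (30 and 40 degrees C by default) is derived from E_a via
#' [q10_ea_convert()]. Values of Q10 near 1 indicate temperature
#' compensation of the clock period.
#'
#' @param periods_by_temperature data.frame with columns `temperature_c`
#'   and `period_h` (replicates allowed), or a list of `(temperature_c,
#'   period_h)` pairs.
#' @param t1_c,t2_c reference temperatures for Q10.
#' @return object of class `arrhenius_fit`: `e_a` (kcal/mol), `e_a_se`,
#'   `ln_a` (intercept), `q10`, `q10_se` (delta method), reference
#'   temperatures, and the underlying `lm` fit.
#' @examples
#' d <- data.frame(temperature_c = c(30, 35, 40),
#'                 period_h = c(24.7, 24.2, 23.8))
#' arrhenius_fit(d)$q10
#' @export
arrhenius_fit <- function(periods_by_temperature, t1_c = 30, t2_c = 40) {
  d <- as.data.frame(periods_by_temperature)
  if (!all(c("temperature_c", "period_h") %in% names(d))) {
    names(d)[1:2] <- c("temperature_c", "period_h")
  }
  if (any(d$period_h <= 0)) stop_kf("validation", "periods must be positive")
  if (length(unique(d$temperature_c)) < 2L) {
    stop_kf("validation", "need >= 2 distinct temperatures")
  }
  x <- 1 / celsius_to_kelvin(d$temperature_c)
  y <- log(24 / d$period_h)
  fit <- lm(y ~ x)
  slope <- coef(fit)[["x"]]
  # exact-law inputs fit perfectly; the summary warning is expected there
  slope_se <- if (nrow(d) > 2L) {
    withCallingHandlers(
      sqrt(vcov(fit)["x", "x"]),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else NA_real_
  e_a <- -slope * R_KCAL
  dinv <- 1 / celsius_to_kelvin(t1_c) - 1 / celsius_to_kelvin(t2_c)
  q10 <- exp(e_a / R_KCAL * dinv)
  structure(list(e_a = e_a,
                 e_a_se = slope_se * R_KCAL,
                 ln_a = coef(fit)[["(Intercept)"]],
                 q10 = q10,
                 q10_se = if (is.na(slope_se)) NA_real_
                 else q10 * dinv * slope_se,
                 t1_c = t1_c, t2_c = t2_c,
                 fit = fit, data = d),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d points, %d temperatures\n",
              nrow(x$data), length(unique(x$data$temperature_c))))
  cat(sprintf("  E_a = %.3f%s kcal/mol\n", x$e_a,
              if (is.na(x$e_a_se)) "" else sprintf(" +/- %.3f", x$e_a_se)))
  cat(sprintf("  Q10(%g-%g C) = %.4f%s\n", x$t1_c, x$t2_c, x$q10,
              if (is.na(x$q10_se)) "" else sprintf(" +/- %.4f", x$q10_se)))
  invisible(x)
}

#' Period at a given temperature under an Arrhenius law
#'
#' Helper for generating temperature series: given a reference period at
#' `t_ref_c` and an activation energy, returns the period at `t_c` implied
#' by ln(24/period) being linear in 1/T.
#'
#' @param t_c target temperature (degrees C).
#' @param period_ref_h period at the reference temperature (h).
#' @param e_a activation energy (kcal/mol).
#' @param t_ref_c reference temperature (degrees C).
#' @return period in hours.
#' @export
arrhenius_period <- function(t_c, period_ref_h, e_a, t_ref_c = 30) {
  period_ref_h * exp(e_a / R_KCAL *
                       (1 / celsius_to_kelvin(t_c) -
                          1 / celsius_to_kelvin(t_ref_c)))
}
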