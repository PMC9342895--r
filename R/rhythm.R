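#' Phosphorylated fraction of a phosphostate time course
#'
#' ST is the only unphosphorylated state, so the fraction of phosphorylated
#' KaiC at each time is A_SpT + A_pSpT + A_pST = 1 - A_ST. This is the
#' quantity read off phosphorylation gels and used for period estimation.
#'
#' @param abund an `abundance_timecourse`.
#' @param states which states count as phosphorylated (configurable in case
#'   a gel quantification merges bands differently).
#' @return a data.frame of class `phospho_fraction_trace` with columns
#'   `time_h`, `fraction`.
#' @export
phosphorylated_fraction <- function(abund,
                                    states = c("SpT", "pSpT", "pST")) {
  stopifnot(inherits(abund, "abundance_timecourse"))
  if (!all(states %in% KAIC_STATES)) {
    stop_kf("validation", "unknown state in 'states'")
  }
  frac <- rowSums(abundance_matrix(abund)[, paste0("A_", states), drop = FALSE])
  df <- data.frame(time_h = abund$time_h, fraction = frac)
  class(df) <- c("phospho_fraction_trace", "data.frame")
  df
}

#' Estimate rhythm period by cosine--Fourier fitting
#'
#' Fits \eqn{m + \sum_{k=1}^{K} a_k \cos(2\pi k t/T + \phi_k)} by nonlinear
#' least squares. The single-cosine fit (K = 1) is the primary estimator;
#' refitting with harmonics up to the third serves as a robustness check
#' that the period is insensitive to waveform shape. The period is
#' initialized at the dominant discrete-Fourier frequency and refined by
#' Levenberg-Marquardt on the equivalent sine/cosine parameterization
#' (linear in everything but T).
#'
#' A trace whose fundamental amplitude is indistinguishable from noise
#' (a1 < 2 x SE(a1)) — or which has no spectral peak at all — is flagged
#' arrhythmic and carries no period.
#'
#' @param times,values the time series (times in h, strictly increasing),
#'   or a single data.frame/`fluor_timecourse` in `times` with a time column
#'   and one value column.
#' @param n_harmonics number of harmonics K (1-3).
#' @param detrend remove a linear trend before fitting.
#' @param period_init optional starting period (h); default from the
#'   discrete-Fourier peak.
#' @return object of class `rhythm_fit`: `period` (h), `period_se`,
#'   `amplitudes` and `phases` per harmonic, `mean_level`, `sigma`
#'   (residual SD), `arrhythmic` flag, `n_harmonics`, and `fitted` values.
#' @examples
#' t <- seq(0, 96, by = 0.5)
#' fit <- fit_period(t, 10 + 3 * cos(2 * pi * t / 24.7))
#' fit$period
#' @export
fit_period <- function(times, values = NULL, n_harmonics = 1, detrend = FALSE,
                       period_init = NULL) {
  if (is.null(values)) {
    df <- times
    stopifnot(is.data.frame(df))
    times <- df[[grep("time", names(df), value = TRUE)[1]]]
    values <- df[[setdiff(names(df), grep("time", names(df), value = TRUE))[1]]]
  }
  if (!n_harmonics %in% 1:3) {
    stop_kf("validation", "n_harmonics must be 1, 2 or 3")
  }
  check_times(times)
  n <- length(times)
  if (n < 12L) stop_kf("validation", "need >= 12 points, have %d", n)

  if (detrend) {
    values <- stats::residuals(lm(values ~ times)) + mean(values)
  }

  T0 <- period_init %||% dominant_period(times, values)
  if (is.na(T0) || sd(values) == 0) {
    return(arrhythmic_fit(n_harmonics, values))
  }
  span <- diff(range(times))
  if (span < 2 * T0) {
    stop_kf("validation",
            "time span %.3g h is below two putative periods (T0 = %.3g h)",
            span, T0)
  }

  # b_k cos + c_k sin parameterization: only T enters nonlinearly
  K <- n_harmonics
  harm_design <- function(T) {
    X <- matrix(1, n, 1 + 2 * K)
    for (k in 1:K) {
      X[, 2 * k] <- cos(2 * pi * k * times / T)
      X[, 2 * k + 1] <- sin(2 * pi * k * times / T)
    }
    X
  }
  rss_of_T <- function(T) {
    sum(stats::lsfit(harm_design(T), values, intercept = FALSE)$residuals^2)
  }
  # refine T on a bracket around the spectral peak, then polish jointly
  opt <- optimize(rss_of_T, interval = c(T0 / 1.5, T0 * 1.5), tol = 1e-9)
  T1 <- opt$minimum
  pnames <- c("m", paste0(rep(c("b", "c"), K), rep(1:K, each = 2)), "T")
  start <- as.list(setNames(
    c(stats::lsfit(harm_design(T1), values, intercept = FALSE)$coefficients, T1),
    pnames))
  form <- paste0("values ~ m + ",
                 paste(sprintf("b%d * cos(2*pi*%d*times/T) + c%d * sin(2*pi*%d*times/T)",
                               1:K, 1:K, 1:K, 1:K), collapse = " + "))
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form),
                      data = data.frame(times = times, values = values),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    V <- vcov(fit)
    fitted_vals <- as.numeric(predict(fit))
    sigma <- summary(fit)$sigma
  } else {
    # a start at the exact optimum (noiseless data) can make the nonlinear
    # polish refuse to move; the profiled solution is then already the
    # least-squares estimate, with covariance from the Gauss-Newton
    # linearization sigma^2 (J'J)^-1
    cf <- unlist(start)
    X <- harm_design(T1)
    dT <- rep(0, n)
    for (k in 1:K) {
      wkt <- 2 * pi * k * times / T1
      dT <- dT + (2 * pi * k * times / T1^2) *
        (cf[[paste0("b", k)]] * sin(wkt) - cf[[paste0("c", k)]] * cos(wkt))
    }
    J <- cbind(X, dT)
    colnames(J) <- pnames
    fitted_vals <- as.numeric(X %*% cf[-length(cf)])
    res <- values - fitted_vals
    p <- length(cf)
    sigma <- sqrt(sum(res^2) / max(1L, n - p))
    V <- sigma^2 * solve(crossprod(J))
    dimnames(V) <- list(pnames, pnames)
  }
  amps <- phases <- amp_se <- numeric(K)
  for (k in 1:K) {
    b <- cf[[paste0("b", k)]]; c_ <- cf[[paste0("c", k)]]
    amps[k] <- sqrt(b^2 + c_^2)
    phases[k] <- atan2(-c_, b)   # a cos(wt + phi) = b cos + c sin
    g <- c(b, c_) / amps[k]      # delta method for SE(a_k)
    idx <- c(paste0("b", k), paste0("c", k))
    amp_se[k] <- sqrt(drop(t(g) %*% V[idx, idx] %*% g))
  }
  if (amps[1] < 2 * amp_se[1]) {
    return(arrhythmic_fit(n_harmonics, values))
  }
  structure(list(period = cf[["T"]],
                 period_se = sqrt(V["T", "T"]),
                 amplitudes = amps, amplitude_se = amp_se, phases = phases,
                 mean_level = cf[["m"]],
                 sigma = sigma,
                 arrhythmic = FALSE, n_harmonics = K,
                 fitted = fitted_vals, times = times),
            class = "rhythm_fit")
}

arrhythmic_fit <- function(K, values) {
  structure(list(period = NA_real_, period_se = NA_real_,
                 amplitudes = rep(NA_real_, K), amplitude_se = rep(NA_real_, K),
                 phases = rep(NA_real_, K),
                 mean_level = mean(values), sigma = sd(values),
                 arrhythmic = TRUE, n_harmonics = K,
                 fitted = rep(mean(values), length(values)), times = NULL),
            class = "rhythm_fit")
}

# dominant non-zero frequency of the (interpolated, uniform) series
dominant_period <- function(times, values) {
  tt <- seq(min(times), max(times), length.out = max(length(times), 64L))
  yy <- approx(times, values, xout = tt)$y
  yy <- yy - mean(yy)
  if (all(yy == 0)) return(NA_real_)
  p <- Mod(fft(yy))^2
  half <- 2:floor(length(yy) / 2)
  k <- half[which.max(p[half])] - 1L
  span <- diff(range(tt))
  span / k
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (x$arrhythmic) {
    cat("Rhythm fit: arrhythmic (fundamental amplitude not above noise)\n")
  } else {
    cat(sprintf("Rhythm fit (K = %d): period %.3f +/- %.3f h, amplitude %.3g, mean %.3g\n",
                x$n_harmonics, x$period, x$period_se, x$amplitudes[1],
                x$mean_level))
  }
  invisible(x)
}

#' Peak-to-trough amplitude of a trace
#'
#' Max minus min of the raw values (default) or of a fitted harmonic curve,
#' the convention used when quoting how much a probe substitution enhances
#' the oscillation amplitude.
#'
#' @param times,values the time series (or a data.frame in `times`).
#' @param use_fit use the [fit_period()] fitted curve instead of raw values.
#' @param n_harmonics harmonics for the fitted-curve variant.
#' @return the amplitude in signal units.
#' @export
amplitude_minmax <- function(times, values = NULL, use_fit = FALSE,
                             n_harmonics = 1) {
  if (is.null(values)) {
    df <- times
    stopifnot(is.data.frame(df))
    times <- df[[grep("time", names(df), value = TRUE)[1]]]
    values <- df[[setdiff(names(df), grep("time", names(df), value = TRUE))[1]]]
  }
  if (length(values) < 2L) stop_kf("validation", "need >= 2 points")
  if (use_fit) {
    fit <- fit_period(times, values, n_harmonics = n_harmonics)
    if (fit$arrhythmic) return(0)
    values <- fit$fitted
  }
  max(values) - min(values)
}
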