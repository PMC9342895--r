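#' Fit per-state fluorescence intensities by least squares
#'
#' Recovers the intrinsic intensities (F_SpT, F_pSpT, F_pST, F_ST) by
#' ordinary least squares on the linear model
#' F_app(t) = sum_i F_i A_i(t) [+ offset]. Abundances, the smoother and
#' more sparsely sampled measurement, are linearly interpolated to the
#' fluorescence timestamps; extrapolation beyond the abundance time range
#' is never performed (those fluorescence points are dropped).
#'
#' A design condition number above `kappa_max` raises an identifiability
#' error naming the near-collinear columns rather than returning
#' meaningless coefficients. Note that because the four abundance columns
#' sum to one at every time point, a free offset column is *exactly*
#' collinear with them: a constant background is confounded with a uniform
#' shift of all four F_i and cannot be fitted jointly from simplex
#' abundances. `with_offset = TRUE` therefore fails with the
#' identifiability error unless the abundance matrix genuinely breaks the
#' unit-sum constraint; constant backgrounds (e.g. KaiA fluorescence in
#' reconstituted reactions) are instead estimated in a second stage with
#' the F_i held fixed — see [fit_offset()].
#'
#' @param fluor a [fluor_timecourse()].
#' @param abund an `abundance_timecourse`; rows deviating from unit sum by
#'   up to `sum_tol` are renormalized with a message.
#' @param with_offset include a free constant column (see Details; defaults
#'   to `FALSE`, the identifiable formulation).
#' @param non_negative constrain all coefficients to be >= 0 (off by
#'   default; the plain OLS formulation imposes no constraint).
#' @param sum_tol tolerated deviation of abundance row sums from 1
#'   (default 0.02, accommodating gel-quantification error).
#' @param kappa_max identifiability threshold on the design condition number.
#' @return a [state_fluorescence()] with standard errors from the fit
#'   covariance, residual SD, and the design condition number.
#' @examples
#' osc <- oscillation_model(period = 24.7)
#' A <- generate_oscillation_abundances(osc, seq(0, 96, by = 0.5))
#' truth <- state_fluorescence(c(SpT = 40, pSpT = 8, pST = 20, ST = 38))
#' fit <- fit_state_fluorescence(compose_fapp(truth, A), A)
#' fit$f_values
#' @seealso [fit_offset()] for background estimation with fixed F_i.
#' @export
fit_state_fluorescence <- function(fluor, abund, with_offset = FALSE,
                                   non_negative = FALSE, sum_tol = 0.02,
                                   kappa_max = 1e6) {
  stopifnot(inherits(fluor, "fluor_timecourse"),
            inherits(abund, "abundance_timecourse"))
  abund <- ingest_abundances(abund, sum_tol)
  condition <- attr(fluor, "condition") %||% NA_character_

  al <- align_design(fluor, abund, n_min = max(5L, 5L + as.integer(with_offset)))
  tt <- al$tt; y <- al$y; X <- al$X
  if (with_offset) X <- cbind(X, offset = 1)

  kap <- kappa(X, exact = TRUE)
  if (!is.finite(kap) || kap > kappa_max) {
    # name the flattest direction of the design
    v <- svd(scale(X, center = FALSE, scale = sqrt(colSums(X^2))))$v
    load <- abs(v[, ncol(v)])
    worst <- order(load, decreasing = TRUE)[1:2]
    stop_kf("identifiability",
            "design condition number %.3g exceeds %g; columns '%s' and '%s' are nearly collinear%s",
            kap, kappa_max, colnames(X)[worst[1]], colnames(X)[worst[2]],
            if (with_offset)
              " (a free offset is confounded with unit-sum abundances; use fit_offset())"
            else "")
  }

  if (non_negative) {
    fit <- nnls_fit(X, y)
    beta <- fit$beta; se <- rep(NA_real_, ncol(X)); sigma <- fit$sigma
  } else {
    fit <- lm(y ~ X - 1)
    # summary.lm warns on the (legitimate) noiseless synthetic case
    fs <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    beta <- setNames(coef(fit), colnames(X))
    se <- setNames(fs$coefficients[, "Std. Error"], colnames(X))
    sigma <- fs$sigma
  }
  f <- setNames(beta[paste0("A_", KAIC_STATES)], KAIC_STATES)
  fse <- setNames(se[paste0("A_", KAIC_STATES)], KAIC_STATES)
  state_fluorescence(
    f_values = f, f_se = fse,
    offset = if (with_offset) unname(beta["offset"]) else 0,
    offset_se = if (with_offset) unname(se["offset"]) else NA_real_,
    construct = attr(fluor, "construct") %||% NA_character_,
    condition = condition, sigma = sigma, kappa = kap)
}

# interpolate abundances onto fluorescence timestamps; never extrapolate
align_design <- function(fluor, abund, n_min = 5L) {
  keep <- fluor$time_h >= min(abund$time_h) & fluor$time_h <= max(abund$time_h)
  tt <- fluor$time_h[keep]
  if (length(tt) < n_min) {
    stop_kf("validation",
            "need >= %d fluorescence points inside the abundance time range (have %d)",
            n_min, length(tt))
  }
  X <- vapply(paste0("A_", KAIC_STATES), function(col) {
    approx(abund$time_h, abund[[col]], xout = tt)$y
  }, numeric(length(tt)))
  X <- matrix(X, nrow = length(tt),
              dimnames = list(NULL, paste0("A_", KAIC_STATES)))
  list(tt = tt, y = fluor$f_app[keep], X = X)
}

#' Estimate a constant background offset with fixed state intensities
#'
#' Second stage of the two-stage background estimation: given per-state
#' intensities F_i (typically fitted from an offset-free KaiC-alone
#' auto-dephosphorylation experiment), the constant background of a trace —
#' e.g. the KaiA fluorescence contribution in a reconstituted oscillator
#' reaction — is the mean residual
#' offset = mean(F_app(t) - sum_i F_i A_i(t)), which is its least-squares
#' estimate with F fixed. This sidesteps the exact collinearity that makes
#' a jointly fitted offset unidentifiable (see
#' [fit_state_fluorescence()]).
#'
#' @param fluor a [fluor_timecourse()] containing the background.
#' @param abund matching `abundance_timecourse`.
#' @param state_f [state_fluorescence()] providing the fixed F_i.
#' @param sum_tol abundance row-sum tolerance.
#' @return a [state_fluorescence()] carrying the input F_i together with
#'   the estimated `offset`, its standard error, and the residual SD around
#'   the offset-corrected model.
#' @export
fit_offset <- function(fluor, abund, state_f, sum_tol = 0.02) {
  stopifnot(inherits(fluor, "fluor_timecourse"),
            inherits(abund, "abundance_timecourse"),
            inherits(state_f, "state_fluorescence"))
  abund <- ingest_abundances(abund, sum_tol)
  al <- align_design(fluor, abund, n_min = 3L)
  r <- al$y - as.numeric(al$X %*% state_f$f_values)
  n <- length(r)
  state_fluorescence(
    f_values = state_f$f_values, f_se = state_f$f_se,
    offset = mean(r),
    offset_se = if (n > 1L) sd(r) / sqrt(n) else NA_real_,
    construct = attr(fluor, "construct") %||% state_f$construct,
    condition = attr(fluor, "condition") %||% NA_character_,
    sigma = if (n > 1L) sd(r) else NA_real_, kappa = state_f$kappa)
}

# projected-gradient NNLS; small fixed problem (<= 5 coefficients)
nnls_fit <- function(X, y) {
  beta <- stats::coef(lm(y ~ X - 1))
  beta <- pmax(beta, 0)
  obj <- function(b) sum((y - X %*% b)^2)
  opt <- nlminb(beta, obj, lower = rep(0, ncol(X)))
  res <- y - X %*% opt$par
  list(beta = setNames(opt$par, colnames(X)),
       sigma = sqrt(sum(res^2) / max(1, length(y) - ncol(X))))
}

ingest_abundances <- function(abund, sum_tol = 0.02) {
  A <- abundance_matrix(abund)
  s <- rowSums(A)
  bad <- which(abs(s - 1) > sum_tol)
  if (length(bad)) {
    stop_kf("validation",
            "abundance rows %s deviate from unit sum by more than %g (max dev %.3g)",
            paste(utils::head(bad, 5), collapse = ", "), sum_tol,
            max(abs(s - 1)))
  }
  off <- which(abs(s - 1) > 1e-9)
  if (length(off)) {
    message(sprintf("renormalizing %d abundance row(s) (max deviation %.3g)",
                    length(off), max(abs(s - 1))))
    abund[paste0("A_", KAIC_STATES)] <- A / s
  }
  abund
}

#' Extract the W419 probe contribution by construct subtraction
#'
#' The engineered tryptophan's per-state fluorescence F^W419 is the
#' difference between the per-state intensities of the probe-bearing
#' construct (F419W) and the base construct, state by state; standard
#' errors combine in quadrature.
#'
#' @param mutant [state_fluorescence()] for the F419W-bearing construct.
#' @param base [state_fluorescence()] for the matched base construct.
#' @return object of class `w419_contribution`: named differences `f_w419`
#'   with propagated SEs.
#' @export
extract_w419 <- function(mutant, base) {
  stopifnot(inherits(mutant, "state_fluorescence"),
            inherits(base, "state_fluorescence"))
  if (!identical(names(mutant$f_values), names(base$f_values))) {
    stop_kf("validation", "state sets of the two fits do not match")
  }
  if (!is.na(mutant$condition) && !is.na(base$condition) &&
      mutant$condition != base$condition) {
    stop_kf("validation", "constructs were measured under different conditions")
  }
  structure(list(
    f_w419 = mutant$f_values - base$f_values,
    f_w419_se = sqrt(ifelse(is.na(mutant$f_se), 0, mutant$f_se)^2 +
                       ifelse(is.na(base$f_se), 0, base$f_se)^2),
    mutant = mutant$construct, base = base$construct),
    class = "w419_contribution")
}

#' @export
print.w419_contribution <- function(x, ...) {
  cat(sprintf("W419 contribution (%s - %s)\n", x$mutant, x$base))
  for (s in KAIC_STATES) {
    cat(sprintf("  F^W419_%-5s = %8.3f +/- %.3f\n", s, x$f_w419[[s]],
                x$f_w419_se[[s]]))
  }
  invisible(x)
}

#' Forward-simulate an apparent-fluorescence trace
#'
#' Deterministic evaluation of sum_i F_i A_i(t) + offset on the abundance
#' time grid — the curve overlaid on observed traces to judge how well the
#' fitted intensities explain the data.
#'
#' @param state_f a [state_fluorescence()].
#' @param abund an `abundance_timecourse`.
#' @return a [fluor_timecourse()].
#' @export
simulate_fapp <- function(state_f, abund) {
  compose_fapp(state_f, abund, noise_sigma = 0)
}

#' Goodness of fit between observed and simulated traces
#'
#' @param observed,simulated [fluor_timecourse()] objects; `simulated` is
#'   linearly interpolated to the observed timestamps where grids differ.
#' @return list with `rmsd`, `pearson_r`, `n`, and a `residuals` data.frame
#'   (`time_h`, `residual`) for phase-resolved inspection.
#' @export
compare_fit <- function(observed, simulated) {
  stopifnot(inherits(observed, "fluor_timecourse"),
            inherits(simulated, "fluor_timecourse"))
  keep <- observed$time_h >= min(simulated$time_h) &
    observed$time_h <= max(simulated$time_h)
  tt <- observed$time_h[keep]
  if (length(tt) < 3L) {
    stop_kf("validation", "fewer than 3 common time points")
  }
  sim <- approx(simulated$time_h, simulated$f_app, xout = tt)$y
  res <- observed$f_app[keep] - sim
  list(rmsd = sqrt(mean(res^2)),
       pearson_r = if (sd(sim) == 0 || sd(observed$f_app[keep]) == 0) NA_real_
       else stats::cor(observed$f_app[keep], sim),
       n = length(tt),
       residuals = data.frame(time_h = tt, residual = res))
}
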