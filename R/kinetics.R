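#' First-order kinetic model of KaiC phosphostate interconversion
#'
#' Describes mass-conserving first-order exchange among the four
#' phosphostates. The shipped default is the auto-dephosphorylation relaxation
#' observed when KaiC is incubated alone (after a shift from ice to 30 degrees
#' C): the doubly phosphorylated pSpT state drains through pST to the
#' unphosphorylated ST state, and SpT dephosphorylates to ST directly. Rates
#' are phenomenological fixtures, not measured constants.
#'
#' @param rates named numeric vector of first-order rate constants (h^-1).
#'   Names are `"source->sink"` pairs over the states
#'   `r paste(KAIC_STATES, collapse = ", ")`, e.g. `"pSpT->pST"`.
#' @param initial initial abundance 4-vector on the simplex, named or in the
#'   canonical order SpT, pSpT, pST, ST.
#' @return an object of class `phospho_kinetic_model` with elements
#'   `rate_matrix` (4x4 generator, columns summing to zero) and `initial`.
#' @examples
#' m <- phospho_kinetic_model()
#' generate_autodephos_abundances(m, times = c(0, 6, 12, 24))
#' @export
phospho_kinetic_model <- function(rates = c("pSpT->pST" = 0.30,
                                            "pST->ST"   = 0.12,
                                            "SpT->ST"   = 0.50),
                                  initial = c(SpT = 0.25, pSpT = 0.45,
                                              pST = 0.15, ST = 0.15)) {
  if (length(rates) && is.null(names(rates))) {
    stop_kf("validation", "rates must be named 'source->sink'")
  }
  if (any(rates < 0)) {
    stop_kf("validation", "rate constants must be non-negative")
  }
  initial <- as_state_vector(initial, "initial abundances")
  check_simplex(initial, tol = 1e-9, what = "initial abundances")

  K <- matrix(0, 4, 4, dimnames = list(KAIC_STATES, KAIC_STATES))
  for (nm in names(rates)) {
    pair <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% KAIC_STATES) || pair[1] == pair[2]) {
      stop_kf("validation", "bad rate name '%s' (expect 'source->sink')", nm)
    }
    K[pair[2], pair[1]] <- K[pair[2], pair[1]] + rates[[nm]]
  }
  diag(K) <- diag(K) - colSums(K)
  structure(list(rate_matrix = K, initial = initial, rates = rates),
            class = "phospho_kinetic_model")
}

as_state_vector <- function(x, what = "vector") {
  x <- unlist(x)
  if (length(x) != 4L) stop_kf("validation", "%s must have length 4", what)
  if (!is.null(names(x))) {
    if (!setequal(names(x), KAIC_STATES)) {
      stop_kf("validation", "%s names must be %s", what,
              paste(KAIC_STATES, collapse = ", "))
    }
    x <- x[KAIC_STATES]
  } else {
    names(x) <- KAIC_STATES
  }
  x
}

#' Simulate auto-dephosphorylation abundance kinetics
#'
#' Solves the linear system dA/dt = K A exactly (matrix exponential of the
#' generator) at the requested times, with the initial condition applied at
#' t = 0. Total abundance is conserved because the generator's columns sum to
#' zero.
#'
#' @param model a [phospho_kinetic_model()].
#' @param times strictly increasing times in hours, `times[1] >= 0`.
#' @return an `abundance_timecourse`: a data.frame with columns `time_h`,
#'   `A_SpT`, `A_pSpT`, `A_pST`, `A_ST`, each row on the simplex.
#' @export
generate_autodephos_abundances <- function(model, times) {
  stopifnot(inherits(model, "phospho_kinetic_model"))
  check_times(times)
  K <- model$rate_matrix
  A <- t(vapply(times, function(t) {
    as.numeric(Matrix::expm(K * t) %*% model$initial)
  }, numeric(4)))
  new_abundance_timecourse(times, A)
}

check_times <- function(times) {
  if (length(times) < 1L || anyNA(times)) {
    stop_kf("validation", "times must be non-empty and finite")
  }
  if (times[1] < 0) stop_kf("validation", "times must start at >= 0 h")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_kf("validation", "times must be strictly increasing")
  }
  invisible(times)
}

new_abundance_timecourse <- function(times, A, renormalize = FALSE) {
  dimnames(A) <- list(NULL, paste0("A_", KAIC_STATES))
  df <- data.frame(time_h = times, A, check.names = FALSE)
  rownames(df) <- NULL
  class(df) <- c("abundance_timecourse", "data.frame")
  if (renormalize) {
    s <- rowSums(abundance_matrix(df))
    df[paste0("A_", KAIC_STATES)] <- abundance_matrix(df) / s
  }
  df
}

#' Resample an abundance time course onto a new time grid
#'
#' Linear interpolation of each state's trajectory; because interpolation is
#' linear, resampled rows still sum to 1 exactly. Extrapolation outside the
#' original time range is an error.
#'
#' @param abund an `abundance_timecourse`.
#' @param times new strictly increasing time grid (h) inside the original
#'   range.
#' @return an `abundance_timecourse` on `times`.
#' @export
resample_abundances <- function(abund, times) {
  stopifnot(inherits(abund, "abundance_timecourse"))
  check_times(times)
  if (min(times) < min(abund$time_h) || max(times) > max(abund$time_h)) {
    stop_kf("validation", "resampling grid extends beyond the abundance range")
  }
  A <- vapply(paste0("A_", KAIC_STATES), function(col) {
    approx(abund$time_h, abund[[col]], xout = times)$y
  }, numeric(length(times)))
  new_abundance_timecourse(times, matrix(A, nrow = length(times)))
}

#' Extract the time-by-state abundance matrix
#'
#' @param abund an `abundance_timecourse`.
#' @return numeric matrix with one column per state in canonical order.
#' @export
abundance_matrix <- function(abund) {
  A <- as.matrix(abund[paste0("A_", KAIC_STATES)])
  rownames(A) <- NULL
  A
}

#' @export
print.phospho_kinetic_model <- function(x, ...) {
  cat("Phosphostate kinetic model\n")
  cat("  rates (h^-1):",
      paste(sprintf("%s = %g", names(x$rates), x$rates), collapse = ", "),
      "\n")
  cat("  initial:",
      paste(sprintf("%s = %.3f", KAIC_STATES, x$initial), collapse = ", "),
      "\n")
  invisible(x)
}
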