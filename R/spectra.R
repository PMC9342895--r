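#' Emission spectrum container
#'
#' A wavelength-indexed fluorescence trace with sample metadata. Wavelengths
#' must be strictly increasing and free of missing values; a regular 1 nm
#' grid is the expected instrument output.
#'
#' @param wavelength_nm strictly increasing wavelengths (nm).
#' @param intensity fluorescence intensities, same length.
#' @param meta named list of metadata (sample, construct, state, replicate,
#'   temperature_c, concentration, nata_reference_signal, normalized, ...).
#' @return object of class `emission_spectrum` (a data.frame with columns
#'   `wavelength_nm`, `intensity` and a `meta` attribute).
#' @export
emission_spectrum <- function(wavelength_nm, intensity, meta = list()) {
  if (length(wavelength_nm) != length(intensity)) {
    stop_kf("validation", "wavelength and intensity lengths differ")
  }
  if (anyNA(wavelength_nm) || anyNA(intensity)) {
    stop_kf("validation", "spectrum contains missing values")
  }
  if (length(wavelength_nm) > 1L && any(diff(wavelength_nm) <= 0)) {
    stop_kf("validation", "wavelengths must be strictly increasing")
  }
  df <- data.frame(wavelength_nm = wavelength_nm, intensity = intensity)
  attr(df, "meta") <- meta
  class(df) <- c("emission_spectrum", "data.frame")
  df
}

spectrum_meta <- function(s) attr(s, "meta") %||% list()

#' Normalize a spectrum to protein concentration and a NATA standard
#'
#' Divides every intensity by (concentration x nata_signal), mirroring the
#' instrument convention of reporting Trp emission relative to an
#' N-acetyl-L-tryptophan amide (NATA) standard and per unit protein. A
#' spectrum can be normalized only once; a second attempt is an error.
#'
#' @param raw an [emission_spectrum()].
#' @param concentration protein concentration (mg/ml, > 0); defaults to the
#'   spectrum's metadata.
#' @param nata_signal NATA standard signal (> 0); defaults to metadata.
#' @return the normalized spectrum, with `meta$normalized = TRUE`.
#' @export
normalize_spectrum <- function(raw, concentration = NULL, nata_signal = NULL) {
  stopifnot(inherits(raw, "emission_spectrum"))
  meta <- spectrum_meta(raw)
  if (isTRUE(meta$normalized)) {
    stop_kf("validation", "spectrum is already normalized")
  }
  concentration <- concentration %||% meta$concentration
  nata_signal <- nata_signal %||% meta$nata_reference_signal
  if (is.null(concentration) || is.null(nata_signal)) {
    stop_kf("validation", "concentration and nata_signal are required")
  }
  if (concentration <= 0 || nata_signal <= 0) {
    stop_kf("validation", "normalization divisors must be positive")
  }
  out <- emission_spectrum(raw$wavelength_nm,
                           raw$intensity / (concentration * nata_signal),
                           meta = modifyList(meta, list(
                             normalized = TRUE,
                             concentration = concentration,
                             nata_reference_signal = nata_signal)))
  out
}

#' Integrate a spectrum over an analysis band
#'
#' Trapezoidal integral of the intensity over `[lo, hi]` nm, the band used to
#' define the apparent fluorescence F (default 320-370 nm). Band edges that
#' fall between grid points are included by linear interpolation.
#'
#' @param s an [emission_spectrum()].
#' @param lo,hi band limits in nm; must lie within the spectrum range.
#' @return the integral (units: nm x normalized F).
#' @export
integrate_band <- function(s, lo = 320, hi = 370) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (lo >= hi) stop_kf("validation", "band must satisfy lo < hi")
  w <- s$wavelength_nm
  if (lo < min(w)) {
    stop_kf("band", "lower band edge %.6g nm below spectrum start %.6g nm",
            lo, min(w))
  }
  if (hi > max(w)) {
    stop_kf("band", "upper band edge %.6g nm above spectrum end %.6g nm",
            hi, max(w))
  }
  inside <- w > lo & w < hi
  xx <- c(lo, w[inside], hi)
  yy <- c(approx(w, s$intensity, xout = lo)$y,
          s$intensity[inside],
          approx(w, s$intensity, xout = hi)$y)
  sum(diff(xx) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Locate the emission maximum at sub-grid resolution
#'
#' Finds the grid maximum inside the search window, then refines the peak
#' position by fitting a parabola through that sample and its two
#' neighbours. For a symmetric band on a uniform grid the result is exact.
#' An optional 5-point moving average (off by default) can precede the peak
#' search on noisy spectra.
#'
#' A maximum sitting at the window edge means there is no interior peak
#' (e.g. a monotone spectrum); the result then carries
#' `warning = "edge-maximum"` and a missing `lambda_max`.
#'
#' @param s an [emission_spectrum()].
#' @param window numeric length-2 search window (nm); default the full range.
#' @param smooth logical; apply a 5-point moving average first.
#' @return list with `lambda_max` (nm, NA when flagged), `intensity_max`,
#'   and `warning` (NA or "edge-maximum").
#' @export
find_lambda_max <- function(s, window = NULL, smooth = FALSE) {
  stopifnot(inherits(s, "emission_spectrum"))
  w <- s$wavelength_nm
  y <- s$intensity
  if (smooth && length(y) >= 5L) {
    y <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
    keep <- !is.na(y)
    w <- w[keep]; y <- y[keep]
  }
  if (!is.null(window)) {
    keep <- w >= window[1] & w <= window[2]
    if (sum(keep) < 3L) stop_kf("validation", "search window too narrow")
    w <- w[keep]; y <- y[keep]
  }
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    return(list(lambda_max = NA_real_, intensity_max = y[i],
                warning = "edge-maximum"))
  }
  # parabola through (w[i-1..i+1], y[i-1..i+1]); uniform spacing assumed
  h <- (w[i + 1] - w[i - 1]) / 2
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom * h
  list(lambda_max = w[i] + delta,
       intensity_max = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta / h,
       warning = NA_character_)
}

#' Pointwise difference of two spectra
#'
#' Computes a - b on a common wavelength grid, the operation behind
#' difference spectra of matched constructs with and without the F419W
#' substitution (whose band integral is the W419 contribution F^W419, by
#' linearity of the integral). Grids must be identical unless
#' `interpolate = TRUE`, in which case both spectra are linearly
#' interpolated onto the intersection of their ranges.
#'
#' @param a,b [emission_spectrum()] objects.
#' @param interpolate allow linear interpolation onto a common grid.
#' @return an [emission_spectrum()]; its metadata records both parents.
#' @export
difference_spectrum <- function(a, b, interpolate = FALSE) {
  stopifnot(inherits(a, "emission_spectrum"), inherits(b, "emission_spectrum"))
  if (!interpolate) {
    if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
        any(a$wavelength_nm != b$wavelength_nm)) {
      stop_kf("grid", "wavelength grids differ; set interpolate = TRUE")
    }
    w <- a$wavelength_nm
    d <- a$intensity - b$intensity
  } else {
    lo <- max(min(a$wavelength_nm), min(b$wavelength_nm))
    hi <- min(max(a$wavelength_nm), max(b$wavelength_nm))
    if (lo >= hi) stop_kf("grid", "wavelength ranges do not overlap")
    w <- a$wavelength_nm[a$wavelength_nm >= lo & a$wavelength_nm <= hi]
    d <- approx(a$wavelength_nm, a$intensity, xout = w)$y -
      approx(b$wavelength_nm, b$intensity, xout = w)$y
  }
  emission_spectrum(w, d, meta = list(
    operation = "difference",
    minuend = spectrum_meta(a)$sample %||% "a",
    subtrahend = spectrum_meta(b)$sample %||% "b"))
}

#' Summarize replicate spectra as F and lambda_max (mean +/- SD)
#'
#' For each replicate group, integrates every spectrum over the analysis
#' band and locates its emission maximum, then reports per-group means and
#' SDs — the coordinates of the two-dimensional F vs lambda_max summary used
#' to compare phosphostates. SDs are NA for single replicates.
#'
#' @param groups named list; each element is a list of [emission_spectrum()]
#'   replicates.
#' @param lo,hi analysis band (nm) passed to [integrate_band()].
#' @param window optional search window passed to [find_lambda_max()].
#' @return data.frame with columns `group`, `n`, `F`, `F_sd`, `lambda_max`,
#'   `lambda_max_sd`.
#' @export
summarize_f_lambda <- function(groups, lo = 320, hi = 370, window = NULL) {
  if (!length(groups)) stop_kf("validation", "no replicate groups supplied")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  rows <- lapply(names(groups), function(g) {
    reps <- groups[[g]]
    if (!length(reps)) stop_kf("validation", "replicate group '%s' is empty", g)
    f <- vapply(reps, integrate_band, numeric(1), lo = lo, hi = hi)
    lm_ <- vapply(reps, function(s) find_lambda_max(s, window)$lambda_max,
                  numeric(1))
    data.frame(group = g, n = length(reps),
               F = mean(f), F_sd = if (length(f) > 1L) sd(f) else NA_real_,
               lambda_max = mean(lm_),
               lambda_max_sd = if (length(lm_) > 1L) sd(lm_) else NA_real_)
  })
  do.call(rbind, rows)
}
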