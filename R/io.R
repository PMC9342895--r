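#' Read a time-course CSV (fluorescence or abundance schema)
#'
#' Two documented schemas are auto-detected from the header:
#' \itemize{
#'   \item fluorescence: `time_h, value` plus optional `construct`,
#'     `condition`, `temperature_c`, `replicate` columns;
#'   \item abundance: `time_h, A_SpT, A_pSpT, A_pST, A_ST` plus optional
#'     `replicate`.
#' }
#' Lines starting with `#` (the dialect/version header written by the
#' package's writers) are ignored. Rows are sorted by time. Abundance rows
#' whose sums deviate from 1 by at most `sum_tol` are renormalized with a
#' message; larger deviations are an error naming the offending rows.
#'
#' @param path CSV file path.
#' @param sum_tol tolerance on abundance row sums (default 0.02).
#' @return a [fluor_timecourse()] or an `abundance_timecourse`, by schema.
#' @export
read_timecourse_csv <- function(path, sum_tol = 0.02) {
  if (!file.exists(path)) stop_kf("io", "file not found: %s", path)
  d <- read.csv(path, comment.char = "#", check.names = FALSE)
  abund_cols <- c("time_h", paste0("A_", KAIC_STATES))
  if (all(abund_cols %in% names(d))) {
    d <- d[order(d$time_h), , drop = FALSE]
    check_times(d$time_h)
    out <- new_abundance_timecourse(d$time_h, as.matrix(d[paste0("A_", KAIC_STATES)]))
    return(ingest_abundances(out, sum_tol))
  }
  if (all(c("time_h", "value") %in% names(d))) {
    d <- d[order(d$time_h), , drop = FALSE]
    check_times(d$time_h)
    return(fluor_timecourse(
      d$time_h, d$value,
      temperature_c = if ("temperature_c" %in% names(d)) d$temperature_c[1] else NA_real_,
      construct = if ("construct" %in% names(d)) as.character(d$construct[1]) else NA_character_,
      condition = if ("condition" %in% names(d)) as.character(d$condition[1]) else NA_character_))
  }
  stop_kf("schema",
          "unknown time-course schema in %s; expected columns 'time_h, value' or '%s'",
          path, paste(abund_cols, collapse = ", "))
}

csv_header_comment <- "# kaifluor timecourse CSV v1"

#' Write a fluorescence or abundance time course to CSV
#'
#' Writes the long-format dialects read back by [read_timecourse_csv()],
#' with a version comment line first. Numbers are written at full precision
#' so a write/read round trip is exact to within 1e-12.
#'
#' @param x a [fluor_timecourse()] or `abundance_timecourse`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  if (inherits(x, "fluor_timecourse")) {
    d <- data.frame(time_h = x$time_h, value = x$f_app,
                    construct = attr(x, "construct") %||% NA,
                    condition = attr(x, "condition") %||% NA,
                    temperature_c = attr(x, "temperature_c") %||% NA)
  } else if (inherits(x, "abundance_timecourse")) {
    d <- as.data.frame(unclass(x), check.names = FALSE)
  } else {
    stop_kf("validation", "unsupported object of class %s", class(x)[1])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header_comment, con)
  write.csv(format(d, digits = 17, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read spectra from a long-format CSV
#'
#' Expects columns `wavelength_nm`, `intensity`, and optionally `sample`,
#' `construct`, `state`, `replicate`, `temperature_c`. One file may carry
#' many spectra; they are split on the metadata columns present.
#'
#' @param path CSV path.
#' @return named list of [emission_spectrum()] objects (one per unique
#'   sample/construct/state/replicate combination).
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop_kf("io", "file not found: %s", path)
  d <- read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("wavelength_nm", "intensity")
  if (!all(need %in% names(d))) {
    stop_kf("schema", "spectra CSV must contain columns %s",
            paste(need, collapse = ", "))
  }
  keys <- intersect(c("sample", "construct", "state", "replicate"), names(d))
  keys <- keys[vapply(keys, function(k) !all(is.na(d[[k]])), logical(1))]
  if (!length(keys)) {
    return(list(spectrum = emission_spectrum(d$wavelength_nm, d$intensity)))
  }
  key_df <- d[keys]
  key_df[] <- lapply(key_df, function(x) ifelse(is.na(x), "", as.character(x)))
  split_id <- interaction(key_df, drop = TRUE, sep = "|")
  out <- lapply(split(d, split_id), function(g) {
    g <- g[order(g$wavelength_nm), ]
    meta <- as.list(g[1, keys, drop = FALSE])
    if ("temperature_c" %in% names(g)) meta$temperature_c <- g$temperature_c[1]
    emission_spectrum(g$wavelength_nm, g$intensity, meta = meta)
  })
  out
}

#' Write spectra to a long-format CSV
#'
#' @param spectra a named list of [emission_spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "emission_spectrum")) spectra <- list(spectrum = spectra)
  rows <- lapply(names(spectra), function(nm) {
    s <- spectra[[nm]]
    meta <- spectrum_meta(s)
    data.frame(wavelength_nm = s$wavelength_nm, intensity = s$intensity,
               sample = meta$sample %||% nm,
               construct = meta$construct %||% NA,
               state = meta$state %||% NA,
               replicate = meta$replicate %||% 1)
  })
  d <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# kaifluor spectra CSV v1", con)
  write.csv(format(d, digits = 17, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a flat YAML run configuration
#'
#' @param path YAML file with flat key/value pairs (see [run_config()] for
#'   the recognized keys); must include `rng_seed`.
#' @return a `run_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_kf("io", "config not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration as flat YAML
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
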