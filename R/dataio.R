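# Reading and writing the three-column experiment file dialect:
#   time(s)  temperature(C)  sigma
# Whitespace- or comma-delimited; '#' comments and blank lines skipped;
# a sigma column of all ones means "uncertainty unknown" (unit weights).

#' Read a three-column experiment file
#'
#' Parses a plain-text file with columns time (s), temperature (degrees C)
#' and measurement uncertainty (1 when unknown). Fields may be separated by
#' whitespace or commas; blank lines and lines starting with `#` are
#' skipped. Decimal separator is `.`; anything else is a parse error, not a
#' guess.
#'
#' @param path File path.
#' @return An [observation_series()] on the Celsius scale.
#' @examples
#' f <- tempfile()
#' writeLines(c("# t T sigma", "0 19.9 1", "60 18.2 1", "120 16.9 1"), f)
#' read_exp(f)
#' @export
read_exp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no data lines in ", path, call. = FALSE)
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(raw[i]), "[,[:space:]]+")[[1L]]
    if (length(fields) != 3L)
      stop(sprintf("line %d of %s: expected 3 columns, found %d",
                   i, path, length(fields)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("line %d of %s: non-numeric entry '%s'",
                   i, path, fields[which(is.na(vals))[1L]]), call. = FALSE)
    if (vals[3L] <= 0)
      stop(sprintf("line %d of %s: sigma must be positive, got %g",
                   i, path, vals[3L]), call. = FALSE)
    vals
  })
  m <- do.call(rbind, rows)
  observation_series(m[, 1L], m[, 2L], m[, 3L], scale = "celsius")
}

#' Write an observation series in the experiment file dialect
#'
#' Values are printed at full double precision so that a write/read round
#' trip is bit-exact.
#'
#' @param series An [observation_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exp <- function(series, path) {
  stopifnot(inherits(series, "observation_series"))
  lines <- sprintf("%.17g %.17g %.17g", series$times, series$temps,
                   series$sigmas)
  writeLines(lines, path)
  invisible(path)
}

#' Transform an observation series to dimensionless temperature
#'
#' \eqn{T^*_i = (T_i - T_{eq})/(T_0 - T_{eq})}. Known uncertainties are
#' scaled by \eqn{1/|T_0 - T_{eq}|}; unknown uncertainties (all-ones sigma
#' column) stay at 1.
#'
#' @param series An [observation_series()] on the Celsius scale.
#' @param conditions A [chilling_conditions()].
#' @return An [observation_series()] with `scale = "dimensionless"`.
#' @examples
#' s <- observation_series(c(0, 60), c(19.9, 11.7))
#' to_dimensionless(s, chilling_conditions(19.9, 3.5))
#' @export
to_dimensionless <- function(series, conditions) {
  stopifnot(inherits(series, "observation_series"),
            inherits(conditions, "chilling_conditions"))
  if (series$scale == "dimensionless") return(series)
  span <- conditions$t0 - conditions$teq
  sig <- if (series$sigma_known) series$sigmas / abs(span) else series$sigmas
  observation_series(series$times, (series$temps - conditions$teq) / span,
                     sig, scale = "dimensionless")
}

#' Write a simulated curve as a two-column text file
#'
#' Compatibility writer for external least-squares drivers that exchange
#' simulated curves as plain two-column (time, value) files.
#'
#' @param times Times, s.
#' @param values Simulated values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unsteady <- function(times, values, path) {
  stopifnot(length(times) == length(values))
  writeLines(sprintf("%.17g %.17g", times, values), path)
  invisible(path)
}
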