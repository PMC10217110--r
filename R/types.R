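#' Cylinder geometry
#'
#' A finite solid cylinder with its origin at the geometric centre: radial
#' coordinate \eqn{r \in [0, R]}, axial coordinate \eqn{y \in [-L/2, L/2]}.
#'
#' @param radius Cylinder radius \eqn{R} in metres.
#' @param length Cylinder length \eqn{L} in metres.
#' @return An object of class `cylinder_geometry` with fields `radius` and
#'   `length`.
#' @examples
#' cylinder_geometry(radius = 0.022, length = 0.040)
#' @export
cylinder_geometry <- function(radius, length) {
  stopifnot(is.numeric(radius), length(radius) == 1L,
            is.numeric(length), base::length(length) == 1L)
  if (!is.finite(radius) || radius <= 0)
    stop("`radius` must be a positive finite number (metres)", call. = FALSE)
  if (!is.finite(length) || length <= 0)
    stop("`length` must be a positive finite number (metres)", call. = FALSE)
  structure(list(radius = radius, length = length),
            class = "cylinder_geometry")
}

#' Chilling conditions
#'
#' Initial product temperature and coolant (equilibrium) temperature. Only
#' differences and ratios of temperatures enter the model, so values are in
#' degrees Celsius throughout.
#'
#' @param t0 Initial uniform product temperature, degrees C.
#' @param teq Coolant / equilibrium temperature, degrees C.
#' @return An object of class `chilling_conditions`.
#' @examples
#' chilling_conditions(t0 = 19.9, teq = 3.5)
#' @export
chilling_conditions <- function(t0, teq) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.numeric(teq),
            length(teq) == 1L, is.finite(t0), is.finite(teq))
  if (t0 == teq)
    stop("`t0` and `teq` must differ: the dimensionless transform ",
         "(T - Teq)/(T0 - Teq) is undefined when they are equal",
         call. = FALSE)
  structure(list(t0 = t0, teq = teq), class = "chilling_conditions")
}

#' Thermal parameters of the forward model
#'
#' The two quantities the centre-point cooling curve actually depends on:
#' thermal diffusivity \eqn{\alpha = k/(\rho C_p)} and the reduced heat
#' transfer coefficient \eqn{h' = h_H/(\rho C_p)} (units m/s). The Biot
#' numbers follow as \eqn{Bi_1 = h'R/\alpha} (infinite cylinder) and
#' \eqn{Bi_2 = h'(L/2)/\alpha} (infinite wall).
#'
#' @param alpha Thermal diffusivity, m^2/s.
#' @param h_reduced Reduced heat transfer coefficient \eqn{h_H/(\rho C_p)},
#'   m/s.
#' @return An object of class `thermal_parameters`.
#' @examples
#' thermal_parameters(alpha = 1.43e-7, h_reduced = 6.92 / (1003 * 3918))
#' @export
thermal_parameters <- function(alpha, h_reduced) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(h_reduced), length(h_reduced) == 1L)
  alpha <- unname(alpha); h_reduced <- unname(h_reduced)
  if (!is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be positive and finite (m^2/s)", call. = FALSE)
  if (!is.finite(h_reduced) || h_reduced <= 0)
    stop("`h_reduced` must be positive and finite (m/s)", call. = FALSE)
  structure(list(alpha = alpha, h_reduced = h_reduced),
            class = "thermal_parameters")
}

#' Biot numbers implied by thermal parameters and geometry
#'
#' @param params A [thermal_parameters()] object.
#' @param geometry A [cylinder_geometry()] object.
#' @return Named numeric vector `c(bi1 = , bi2 = )` with the infinite-cylinder
#'   and infinite-wall Biot numbers.
#' @examples
#' p <- thermal_parameters(1.43e-7, 6.92 / (1003 * 3918))
#' g <- cylinder_geometry(0.022, 0.040)
#' param_biot(p, g)
#' @export
param_biot <- function(params, geometry) {
  stopifnot(inherits(params, "thermal_parameters"),
            inherits(geometry, "cylinder_geometry"))
  c(bi1 = params$h_reduced * geometry$radius / params$alpha,
    bi2 = params$h_reduced * (geometry$length / 2) / params$alpha)
}

#' Centre-point observation series
#'
#' The data vector of the inverse problem: times, temperatures at the
#' geometric centre, and measurement uncertainties. A sigma column of all
#' ones is the conventional marker for "uncertainty unknown" (unit weights).
#'
#' @param times Observation times, seconds, nondecreasing.
#' @param temps Temperatures (degrees C, or dimensionless if transformed).
#' @param sigmas Measurement uncertainties, same units as `temps`; a scalar
#'   is recycled. Defaults to 1 (unknown).
#' @param scale Either `"celsius"` or `"dimensionless"`; records which scale
#'   `temps` is on.
#' @return An object of class `observation_series` with fields `times`,
#'   `temps`, `sigmas`, `n`, `sigma_known`, `scale`.
#' @examples
#' observation_series(c(0, 60, 120), c(19.9, 18.2, 16.9))
#' @export
observation_series <- function(times, temps, sigmas = 1,
                               scale = c("celsius", "dimensionless")) {
  scale <- match.arg(scale)
  times <- as.numeric(times); temps <- as.numeric(temps)
  if (length(sigmas) == 1L) sigmas <- rep(as.numeric(sigmas), length(times))
  sigmas <- as.numeric(sigmas)
  n <- length(times)
  if (length(temps) != n || length(sigmas) != n)
    stop("`times`, `temps` and `sigmas` must have equal length", call. = FALSE)
  if (n < 1L) stop("empty observation series", call. = FALSE)
  if (anyNA(times) || anyNA(temps) || anyNA(sigmas))
    stop("observation series contains missing values", call. = FALSE)
  if (is.unsorted(times))
    stop("`times` must be nondecreasing", call. = FALSE)
  if (any(sigmas <= 0))
    stop("all `sigmas` must be positive", call. = FALSE)
  structure(list(times = times, temps = temps, sigmas = sigmas, n = n,
                 sigma_known = !all(sigmas == 1), scale = scale),
            class = "observation_series")
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf("<observation_series> n = %d, t in [%g, %g] s, scale = %s, %s\n",
              x$n, min(x$times), max(x$times), x$scale,
              if (x$sigma_known) "weighted" else "sigma unknown (unit weights)"))
  invisible(x)
}

#' @export
print.cylinder_geometry <- function(x, ...) {
  cat(sprintf("<cylinder_geometry> R = %g m, L = %g m\n", x$radius, x$length))
  invisible(x)
}

#' @export
print.thermal_parameters <- function(x, ...) {
  cat(sprintf("<thermal_parameters> alpha = %g m^2/s, h' = %g m/s\n",
              x$alpha, x$h_reduced))
  invisible(x)
}

#' Coerce an observation series to a data frame
#'
#' @param x An [observation_series()].
#' @param ... Unused.
#' @return A data frame with columns `time`, `temp`, `sigma`.
#' @export
as.data.frame.observation_series <- function(x, ...) {
  data.frame(time = x$times, temp = x$temps, sigma = x$sigmas)
}
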