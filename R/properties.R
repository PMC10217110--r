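# Moisture- and mass-based thermophysical property correlations for
# high-moisture plant tissue, plus Biot-number helpers.

.check_moisture <- function(moisture_wb) {
  stopifnot(is.numeric(moisture_wb), length(moisture_wb) == 1L)
  if (!is.finite(moisture_wb) || moisture_wb < 0 || moisture_wb > 100)
    stop("wet-basis moisture must be in [0, 100] %", call. = FALSE)
  if (moisture_wb < 60 || moisture_wb > 98)
    warning("moisture ", moisture_wb, "% is outside the 60-98% range ",
            "typical of the fresh produce these correlations were fitted on",
            call. = FALSE)
  moisture_wb
}

#' Specific heat from wet-basis moisture (Fikiin)
#'
#' \eqn{C_p = 1382 + 2805\, X_{wb}/100} J/(kg K).
#'
#' @param moisture_wb Wet-basis moisture content, percent, in `[0, 100]`.
#' @return Specific heat, J/(kg K).
#' @examples
#' fikiin_cp(90.4) # 3917.72, printed as 3918
#' @export
fikiin_cp <- function(moisture_wb) {
  1382 + 2805 * .check_moisture(moisture_wb) / 100
}

#' Thermal diffusivity from wet-basis moisture (Riedel)
#'
#' \eqn{\alpha = 0.88\times 10^{-7} + 0.6\times 10^{-7} X_{wb}/100} m^2/s.
#'
#' @inheritParams fikiin_cp
#' @return Thermal diffusivity, m^2/s.
#' @examples
#' riedel_alpha(90.4) # 1.4224e-7
#' @export
riedel_alpha <- function(moisture_wb) {
  0.88e-7 + 0.6e-7 * .check_moisture(moisture_wb) / 100
}

#' Thermal conductivity from wet-basis moisture (Sweat)
#'
#' \eqn{k = 0.148 + 0.493\, X_{wb}/100} W/(m K).
#'
#' @inheritParams fikiin_cp
#' @return Thermal conductivity, W/(m K).
#' @examples
#' sweat_k(90.4) # 0.593672
#' @export
sweat_k <- function(moisture_wb) {
  0.148 + 0.493 * .check_moisture(moisture_wb) / 100
}

#' Density from mass and cylinder volume
#'
#' \eqn{\rho = m / (\pi R^2 L)}.
#'
#' @param mass Sample mass, kg, > 0.
#' @param geometry A [cylinder_geometry()].
#' @return Density, kg/m^3.
#' @examples
#' density_from_mass(0.0610, cylinder_geometry(0.022, 0.040)) # ~1003
#' @export
density_from_mass <- function(mass, geometry) {
  stopifnot(inherits(geometry, "cylinder_geometry"))
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("`mass` must be a positive finite number (kg)", call. = FALSE)
  mass / (pi * geometry$radius^2 * geometry$length)
}

#' Thermal conductivity from diffusivity, density and specific heat
#'
#' \eqn{k = \alpha \rho C_p}.
#'
#' @param alpha Thermal diffusivity, m^2/s.
#' @param rho Density, kg/m^3.
#' @param cp Specific heat, J/(kg K).
#' @return Thermal conductivity, W/(m K).
#' @examples
#' conductivity_from_alpha(1.43e-7, 1003, 3918) # ~0.562
#' @export
conductivity_from_alpha <- function(alpha, rho, cp) {
  stopifnot(is.numeric(alpha), is.numeric(rho), is.numeric(cp))
  if (alpha < 0 || rho <= 0 || cp <= 0)
    stop("require alpha >= 0, rho > 0, cp > 0", call. = FALSE)
  alpha * rho * cp
}

#' Biot numbers from the heat transfer coefficient
#'
#' \eqn{Bi_1 = h_H R / k} (infinite cylinder) and
#' \eqn{Bi_2 = h_H (L/2) / k} (infinite wall).
#'
#' @param h_H Heat transfer coefficient, W/(m^2 K), >= 0.
#' @param geometry A [cylinder_geometry()].
#' @param k Thermal conductivity, W/(m K), > 0.
#' @return Named numeric vector `c(bi1 = , bi2 = )`.
#' @examples
#' biot_numbers(6.92, cylinder_geometry(0.022, 0.040),
#'              conductivity_from_alpha(1.43e-7, 1003, 3918))
#' @export
biot_numbers <- function(h_H, geometry, k) {
  stopifnot(inherits(geometry, "cylinder_geometry"), is.numeric(h_H),
            is.numeric(k))
  if (h_H < 0) stop("`h_H` must be >= 0", call. = FALSE)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  c(bi1 = h_H * geometry$radius / k,
    bi2 = h_H * (geometry$length / 2) / k)
}

#' Property report for a cylindrical sample
#'
#' Convenience wrapper chaining the correlations: density from mass,
#' specific heat (Fikiin), diffusivity (Riedel), conductivity both from the
#' Sweat correlation and from \eqn{\alpha\rho C_p}, and, when `h_H` is
#' given, the Biot numbers (using the unrounded \eqn{\alpha\rho C_p}
#' conductivity) and regime classification.
#'
#' @param moisture_wb Wet-basis moisture, percent.
#' @param mass Sample mass, kg.
#' @param geometry A [cylinder_geometry()].
#' @param alpha Optional thermal diffusivity to use instead of Riedel's.
#' @param h_H Optional heat transfer coefficient, W/(m^2 K).
#' @return Named list of properties.
#' @examples
#' product_properties(90.4, 0.0610, cylinder_geometry(0.022, 0.040),
#'                    alpha = 1.43e-7, h_H = 6.92)
#' @export
product_properties <- function(moisture_wb, mass, geometry, alpha = NULL,
                               h_H = NULL) {
  rho <- density_from_mass(mass, geometry)
  cp <- fikiin_cp(moisture_wb)
  a <- if (is.null(alpha)) riedel_alpha(moisture_wb) else alpha
  k_chain <- conductivity_from_alpha(a, rho, cp)
  out <- list(moisture_wb = moisture_wb, mass = mass, rho = rho, cp = cp,
              alpha = a, k_sweat = sweat_k(moisture_wb), k = k_chain)
  if (!is.null(h_H)) {
    bi <- biot_numbers(h_H, geometry, k_chain)
    out$h_H <- h_H
    out$bi1 <- bi[["bi1"]]
    out$bi2 <- bi[["bi2"]]
    out$regime <- classify_regime(bi[["bi1"]], bi[["bi2"]])
  }
  out
}
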