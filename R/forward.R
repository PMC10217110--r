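# Forward model: the separated series solution
#   T*(r, y, t) = sum_n sum_m A_n A_m J0(mu_n r/R) cos(mu_m y/(L/2))
#                 * exp(-(mu_n^2/R^2 + mu_m^2/(L/2)^2) alpha t)
# The rectangularly truncated double sum factorises exactly into the product
# of the two 1-D sub-problem sums, which is how it is evaluated here.

# 1-D sub-problem partial sum at positions scaled to [0, 1] and times t.
# Returns length(t) values for a single spatial factor `pos` (vector over
# terms: J0(mu r/R) or cos(mu y/(L/2))).
.series_1d <- function(expansion, pos, char_len, alpha, t) {
  w <- expansion$coeffs * pos
  decay <- exp(-outer(expansion$roots^2 / char_len^2, t) * alpha)
  as.vector(crossprod(w, decay))
}

.check_point <- function(r, y, geometry) {
  if (r < 0 || r > geometry$radius)
    stop(sprintf("radial position r = %g outside [0, R = %g]",
                 r, geometry$radius), call. = FALSE)
  if (abs(y) > geometry$length / 2)
    stop(sprintf("axial position y = %g outside [-L/2, L/2] = [%g, %g]",
                 y, -geometry$length / 2, geometry$length / 2), call. = FALSE)
  invisible(TRUE)
}

#' Dimensionless temperature at a point
#'
#' Evaluates \eqn{T^*(r, y, t) = (T - T_{eq})/(T_0 - T_{eq})} from the
#' truncated eigenfunction series. Vectorised over `t`.
#'
#' @param r Radial position, m, in `[0, R]`.
#' @param y Axial position, m, in `[-L/2, L/2]` (origin at mid-plane).
#' @param t Time(s), s, all >= 0.
#' @param geometry A [cylinder_geometry()].
#' @param params A [thermal_parameters()].
#' @param n_terms Series terms per sub-problem (default 200).
#' @return Numeric vector of \eqn{T^*} values, one per element of `t`.
#' @examples
#' g <- cylinder_geometry(0.022, 0.040)
#' p <- thermal_parameters(1.43e-7, 1.761e-6)
#' dimensionless_temperature(0, 0, c(0, 600, 3600), g, p)
#' @export
dimensionless_temperature <- function(r, y, t, geometry, params,
                                      n_terms = 200L) {
  stopifnot(inherits(geometry, "cylinder_geometry"),
            inherits(params, "thermal_parameters"))
  .check_point(r, y, geometry)
  if (any(t < 0)) stop("negative time", call. = FALSE)
  bi <- param_biot(params, geometry)
  R <- geometry$radius; Lh <- geometry$length / 2
  ec <- .cached_expansion("cylinder", bi[["bi1"]], n_terms)
  ew <- .cached_expansion("wall", bi[["bi2"]], n_terms)
  .series_1d(ec, besselJ(ec$roots * r / R, 0), R, params$alpha, t) *
    .series_1d(ew, cos(ew$roots * y / Lh), Lh, params$alpha, t)
}

#' Temperature at a point, degrees C
#'
#' Affine map of the dimensionless solution:
#' \eqn{T = T_{eq} + (T_0 - T_{eq}) T^*}.
#'
#' @inheritParams dimensionless_temperature
#' @param conditions A [chilling_conditions()].
#' @return Numeric vector of temperatures in degrees C.
#' @export
temperature <- function(r, y, t, geometry, params, conditions,
                        n_terms = 200L) {
  stopifnot(inherits(conditions, "chilling_conditions"))
  conditions$teq + (conditions$t0 - conditions$teq) *
    dimensionless_temperature(r, y, t, geometry, params, n_terms)
}

#' Centre-point cooling curve
#'
#' \eqn{T^*(0, 0, t)}: at the centre \eqn{J_0(0) = 1} and \eqn{\cos 0 = 1},
#' so the series reduces to
#' \eqn{\sum_n\sum_m A_n A_m \exp(-(\mu_n^2/R^2 + \mu_m^2/(L/2)^2)\alpha t)}.
#'
#' @param times Nonnegative, nondecreasing times, s.
#' @inheritParams dimensionless_temperature
#' @return Numeric vector of centre dimensionless temperatures.
#' @examples
#' g <- cylinder_geometry(0.022, 0.040)
#' p <- thermal_parameters(1.43e-7, 1.761e-6)
#' center_curve(seq(0, 3600, by = 600), g, p)
#' @export
center_curve <- function(times, geometry, params, n_terms = 200L) {
  if (is.unsorted(times)) stop("`times` must be nondecreasing", call. = FALSE)
  dimensionless_temperature(0, 0, times, geometry, params, n_terms)
}

#' Dimensionless temperature field on an (r, y) grid
#'
#' Evaluates \eqn{T^*} at one time on the tensor grid
#' `r_grid` x `y_grid`. The factorised series makes this an outer product
#' of the two 1-D profiles.
#'
#' @param r_grid Radial positions, m, each in `[0, R]`.
#' @param y_grid Axial positions, m, each in `[-L/2, L/2]`.
#' @param t Single time, s.
#' @inheritParams dimensionless_temperature
#' @return Object of class `temperature_field`: list with `r_grid`,
#'   `y_grid`, `time`, and `values` (matrix, rows = r, cols = y).
#' @examples
#' g <- cylinder_geometry(0.022, 0.040)
#' p <- thermal_parameters(1.43e-7, 1.761e-6)
#' f <- temperature_field(seq(0, 0.022, length.out = 5),
#'                        seq(-0.02, 0.02, length.out = 5), 780, g, p)
#' @export
temperature_field <- function(r_grid, y_grid, t, geometry, params,
                              n_terms = 200L) {
  stopifnot(inherits(geometry, "cylinder_geometry"),
            inherits(params, "thermal_parameters"),
            length(t) == 1L, t >= 0)
  for (r in r_grid) .check_point(r, 0, geometry)
  for (y in y_grid) .check_point(0, y, geometry)
  bi <- param_biot(params, geometry)
  R <- geometry$radius; Lh <- geometry$length / 2
  ec <- .cached_expansion("cylinder", bi[["bi1"]], n_terms)
  ew <- .cached_expansion("wall", bi[["bi2"]], n_terms)
  dc <- ec$coeffs * exp(-ec$roots^2 / R^2 * params$alpha * t)
  dw <- ew$coeffs * exp(-ew$roots^2 / Lh^2 * params$alpha * t)
  prof_r <- as.vector(besselJ(outer(r_grid / R, ec$roots), 0) %*% dc)
  prof_y <- as.vector(cos(outer(y_grid / Lh, ew$roots)) %*% dw)
  structure(list(r_grid = r_grid, y_grid = y_grid, time = t,
                 values = outer(prof_r, prof_y)),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %d x %d grid at t = %g s; T* in [%.4f, %.4f]\n",
              length(x$r_grid), length(x$y_grid), x$time,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Coerce a temperature field to long-format data frame
#'
#' @param x A `temperature_field`.
#' @param ... Unused.
#' @return Data frame with columns `r`, `y`, `t`, `T_star`.
#' @export
as.data.frame.temperature_field <- function(x, ...) {
  data.frame(r = rep(x$r_grid, times = length(x$y_grid)),
             y = rep(x$y_grid, each = length(x$r_grid)),
             t = x$time,
             T_star = as.vector(x$values))
}

#' Write a temperature field as long-format CSV
#'
#' @param field A `temperature_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  write.csv(as.data.frame(field), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Maximum centre-surface dimensionless temperature gap
#'
#' Scans \eqn{T^*(0,0,t) - T^*(R,0,t)} on the grid `{0, dt, ..., t_max}`
#' and returns the maximum lag of the centre behind the lateral surface and
#' the time at which it occurs.
#'
#' @param geometry A [cylinder_geometry()].
#' @param params A [thermal_parameters()].
#' @param t_max Scan end time, s (> 0).
#' @param dt Scan step, s (> 0); default 1.
#' @param n_terms Series terms per sub-problem.
#' @return List with `gap` (dimensionless), `t_at_max` (s), and the scanned
#'   `times`/`gaps` vectors.
#' @examples
#' g <- cylinder_geometry(0.022, 0.040)
#' p <- thermal_parameters(1.43e-7, 1.761e-6)
#' max_center_surface_gap(g, p, t_max = 1800, dt = 10, n_terms = 60)
#' @export
max_center_surface_gap <- function(geometry, params, t_max = 3600, dt = 1,
                                   n_terms = 200L) {
  stopifnot(t_max > 0, dt > 0)
  times <- seq(0, t_max, by = dt)
  bi <- param_biot(params, geometry)
  R <- geometry$radius; Lh <- geometry$length / 2
  ec <- .cached_expansion("cylinder", bi[["bi1"]], n_terms)
  ew <- .cached_expansion("wall", bi[["bi2"]], n_terms)
  wall0 <- .series_1d(ew, rep(1, ew$n_terms), Lh, params$alpha, times)
  cyl0 <- .series_1d(ec, rep(1, ec$n_terms), R, params$alpha, times)
  cylR <- .series_1d(ec, besselJ(ec$roots, 0), R, params$alpha, times)
  gaps <- (cyl0 - cylR) * wall0
  i <- which.max(gaps)
  list(gap = gaps[i], t_at_max = times[i], times = times, gaps = gaps)
}

#' Classify the heat-transfer regime from the Biot numbers
#'
#' Below 0.1 on both axes the internal gradients are negligible (lumped
#' capacitance); above 40 on both the surface follows the coolant
#' (first-kind boundary, practically infinite Biot); otherwise the
#' third-kind convective model is required.
#'
#' @param bi1 Infinite-cylinder Biot number, >= 0.
#' @param bi2 Infinite-wall Biot number, >= 0.
#' @return One of `"lumped"`, `"third_kind"`, `"first_kind"`.
#' @examples
#' classify_regime(0.271, 0.246) # "third_kind"
#' @export
classify_regime <- function(bi1, bi2) {
  stopifnot(is.numeric(bi1), is.numeric(bi2))
  if (bi1 < 0 || bi2 < 0) stop("Biot numbers must be >= 0", call. = FALSE)
  if (bi1 < 0.1 && bi2 < 0.1) "lumped"
  else if (bi1 > 40 && bi2 > 40) "first_kind"
  else "third_kind"
}
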