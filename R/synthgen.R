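# Synthetic centre-point cooling curves with known ground truth, for
# testing the estimator and Monte-Carlo coverage calibration.

#' Synthetic cooling-curve design
#'
#' Bundles geometry, chilling conditions, true thermal parameters, sampling
#' times, noise level and seed for [generate_observations()].
#'
#' @param geometry A [cylinder_geometry()].
#' @param conditions A [chilling_conditions()].
#' @param truth A [thermal_parameters()] object: the ground truth.
#' @param times Sampling times, s, nondecreasing.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0) on the
#'   scale given by `noise_scale`.
#' @param noise_scale `"dimensionless"` (default: noise added to \eqn{T^*})
#'   or `"celsius"`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Object of class `synth_design`.
#' @export
synth_design <- function(geometry, conditions, truth, times, noise_sd = 0,
                         noise_scale = c("dimensionless", "celsius"),
                         seed = NULL) {
  noise_scale <- match.arg(noise_scale)
  stopifnot(inherits(geometry, "cylinder_geometry"),
            inherits(conditions, "chilling_conditions"),
            inherits(truth, "thermal_parameters"),
            is.numeric(times), length(times) >= 1L)
  if (is.unsorted(times) || any(times < 0))
    stop("`times` must be nonnegative and nondecreasing", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(geometry = geometry, conditions = conditions, truth = truth,
                 times = as.numeric(times), noise_sd = noise_sd,
                 noise_scale = noise_scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synth_design")
}

#' @export
print.synth_design <- function(x, ...) {
  cat(sprintf(
    "<synth_design> n = %d times in [%g, %g] s; truth alpha = %g, h' = %g;\n  noise_sd = %g (%s), seed = %s\n",
    length(x$times), min(x$times), max(x$times), x$truth$alpha,
    x$truth$h_reduced, x$noise_sd, x$noise_scale,
    if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Generate a synthetic observation series
#'
#' Evaluates the exact centre-point curve at the design's truth and adds
#' i.i.d. Gaussian noise. The output is on the Celsius scale (the
#' experiment-file dialect); dimensionless noise of sd \eqn{s} maps to
#' Celsius noise of sd \eqn{s\,|T_0 - T_{eq}|}. The sigma column carries
#' the true noise sd on the Celsius scale, or 1 ("unknown") when
#' `noise_sd = 0`.
#'
#' @param design A [synth_design()].
#' @param n_terms Series terms per sub-problem (default 200).
#' @return An [observation_series()] (Celsius scale) with attribute
#'   `"seed"` recording the seed used.
#' @examples
#' d <- carrot_design(noise_sd = 0.005, seed = 1)
#' generate_observations(d, n_terms = 60)
#' @export
generate_observations <- function(design, n_terms = 200L) {
  stopifnot(inherits(design, "synth_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  tstar <- center_curve(design$times, design$geometry, design$truth, n_terms)
  span <- design$conditions$t0 - design$conditions$teq
  temps <- design$conditions$teq + span * tstar
  sd_c <- if (design$noise_scale == "dimensionless")
            design$noise_sd * abs(span) else design$noise_sd
  if (design$noise_sd > 0)
    temps <- temps + rnorm(length(temps), 0, sd_c)
  out <- observation_series(design$times, temps,
                            sigmas = if (design$noise_sd > 0) sd_c else 1,
                            scale = "celsius")
  attr(out, "seed") <- design$seed
  out
}

#' Reference carrot-chilling design
#'
#' The study conditions of the carrot chilling experiment this package
#' models: a cylindrical piece with R = 0.022 m and L = 0.040 m, cooled
#' from 19.9 to 3.5 degrees C, sampled at 49 equally spaced times over one
#' hour, with truth alpha = 1.43e-7 m^2/s and h' = 6.92/(1003 * 3918) m/s
#' (so Bi1 = 0.271, Bi2 = 0.246).
#'
#' @param noise_sd Dimensionless Gaussian noise sd (default 0).
#' @param seed Integer seed or `NULL`.
#' @param n Number of sampling times (default 49).
#' @param t_max Last sampling time, s (default 3600).
#' @return A [synth_design()].
#' @examples
#' carrot_design(noise_sd = 0.005, seed = 42)
#' @export
carrot_design <- function(noise_sd = 0, seed = NULL, n = 49L, t_max = 3600) {
  synth_design(
    geometry = cylinder_geometry(radius = 0.022, length = 0.040),
    conditions = chilling_conditions(t0 = 19.9, teq = 3.5),
    truth = thermal_parameters(alpha = 1.43e-7,
                               h_reduced = 6.92 / (1003 * 3918)),
    times = seq(0, t_max, length.out = n),
    noise_sd = noise_sd, noise_scale = "dimensionless", seed = seed)
}
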