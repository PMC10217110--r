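# Inverse problem: damped weighted least squares on (a1 = alpha, a2 = h').
# Normal equations M dA = C with
#   M[j,k] = sum_i (dTi/daj)(dTi/dak)/sigma_i^2,
#   C[j]   = sum_i delta_i (dTi/daj)/sigma_i^2,  delta_i = Ti_obs - Ti_sim,
# Levenberg damping (M + lambda diag(M)) dA = C, and covariance = inverse of
# the final undamped M.

# Model curve on the scale of the data (dimensionless or degrees C).
.model_curve <- function(params, times, geometry, conditions, scale,
                         n_terms) {
  ts <- center_curve(times, geometry, params, n_terms)
  if (scale == "dimensionless") ts
  else conditions$teq + (conditions$t0 - conditions$teq) * ts
}

#' Residuals of a centre-point fit
#'
#' \eqn{\delta_i = T_i^{obs} - T_i^{sim}} at the geometric centre, on the
#' scale the data is on (weighting by \eqn{1/\sigma_i} is applied in the
#' normal equations, not here).
#'
#' @param params A [thermal_parameters()].
#' @param data An [observation_series()].
#' @param geometry A [cylinder_geometry()].
#' @param conditions A [chilling_conditions()]; needed when the data is in
#'   degrees C, ignored for dimensionless data.
#' @param n_terms Series terms per sub-problem.
#' @return Numeric residual vector of length `data$n`.
#' @export
fit_residuals <- function(params, data, geometry, conditions = NULL,
                          n_terms = 200L) {
  stopifnot(inherits(data, "observation_series"))
  if (data$scale == "celsius" && is.null(conditions))
    stop("`conditions` required for data in degrees C", call. = FALSE)
  data$temps - .model_curve(params, data$times, geometry, conditions,
                            data$scale, n_terms)
}

#' Finite-difference sensitivity matrix
#'
#' Central differences of the simulated centre curve with respect to
#' \eqn{(a_1, a_2) = (\alpha, h')}:
#' \eqn{\partial T_i/\partial a_j \approx
#' [T_i(a_j(1+s)) - T_i(a_j(1-s))]/(2 s a_j)}. A parameter equal to zero
#' falls back to an absolute step of `step`.
#'
#' @inheritParams fit_residuals
#' @param step Relative finite-difference step (default 1e-3).
#' @return `data$n` x 2 Jacobian matrix, columns `alpha` and `h_reduced`.
#' @export
sensitivity_matrix <- function(params, data, geometry, conditions = NULL,
                               step = 1e-3, n_terms = 200L) {
  stopifnot(step > 0, inherits(data, "observation_series"))
  a <- c(params$alpha, params$h_reduced)
  J <- matrix(0, data$n, 2L, dimnames = list(NULL, c("alpha", "h_reduced")))
  for (j in 1:2) {
    h <- if (a[j] != 0) step * abs(a[j]) else step
    ap <- a; ap[j] <- a[j] + h
    am <- a; am[j] <- a[j] - h
    Tp <- .model_curve(thermal_parameters(ap[1], ap[2]), data$times, geometry,
                       conditions, data$scale, n_terms)
    Tm <- .model_curve(thermal_parameters(am[1], am[2]), data$times, geometry,
                       conditions, data$scale, n_terms)
    J[, j] <- (Tp - Tm) / (2 * h)
  }
  J
}

#' Weighted normal equations of the least-squares step
#'
#' @param jacobian N x 2 sensitivity matrix.
#' @param residuals Length-N residual vector.
#' @param sigmas Length-N (or scalar) measurement uncertainties.
#' @return List with `M` (2 x 2) and `C` (length 2).
#' @export
normal_equations <- function(jacobian, residuals, sigmas = 1) {
  stopifnot(is.matrix(jacobian), ncol(jacobian) == 2L,
            nrow(jacobian) == length(residuals))
  w <- 1 / sigmas^2
  if (length(w) == 1L) w <- rep(w, length(residuals))
  stopifnot(length(w) == length(residuals))
  M <- crossprod(jacobian, jacobian * w)
  C <- as.vector(crossprod(jacobian, residuals * w))
  list(M = M, C = C)
}

#' Fit thermal diffusivity and reduced heat transfer coefficient
#'
#' Levenberg-Marquardt weighted least squares on a centre-point cooling
#' curve. Each iteration solves the damped normal equations
#' \eqn{(M + \lambda\,\mathrm{diag}(M))\Delta A = C}; a step that lowers
#' \eqn{\chi^2} is accepted and \eqn{\lambda} divided by 10, otherwise
#' \eqn{\lambda} is multiplied by 10 and the step retried. Convergence is
#' declared when both relative corrections satisfy
#' \eqn{|\Delta a_j / a_j| < } `rel_tol`. Steps that would cross zero are
#' halved until both parameters stay positive.
#'
#' The fit is performed on the dimensionless scale by default (the data is
#' transformed with [to_dimensionless()] if it arrives in degrees C);
#' set `dimensionless = FALSE` to fit raw temperatures.
#'
#' @param data An [observation_series()] with `n >= 3`.
#' @param geometry A [cylinder_geometry()].
#' @param conditions A [chilling_conditions()].
#' @param init Named list or vector with starting values `alpha` (m^2/s)
#'   and `h_reduced` (m/s).
#' @param dimensionless Fit on the \eqn{T^*} scale (default `TRUE`).
#' @param n_terms Series terms per sub-problem (default 200).
#' @param step Relative finite-difference step for sensitivities.
#' @param lambda0 Initial damping parameter (default 1e-3).
#' @param max_iter Maximum accepted iterations (default 100).
#' @param rel_tol Relative-correction convergence tolerance (default 1e-5).
#' @param rho_cp Optional \eqn{\rho C_p} (J/(m^3 K)); when supplied, the
#'   result also reports \eqn{h_H = h' \rho C_p} and \eqn{k = \alpha\rho C_p}
#'   with their uncertainties.
#' @param scale_covariance Rescale the covariance by reduced chi-square
#'   \eqn{\chi^2/(N-2)} (default `FALSE`: the covariance is the plain
#'   inverse of the final undamped normal matrix).
#' @return Object of class `chill_fit`; see [covariance_report()] and
#'   [fit_statistics()] for the derived quantities it carries.
#' @examples
#' g <- cylinder_geometry(0.022, 0.040)
#' cond <- chilling_conditions(19.9, 3.5)
#' d <- synth_design(g, cond, thermal_parameters(1.43e-7, 1.761e-6),
#'                   times = seq(0, 3600, length.out = 25))
#' obs <- generate_observations(d, n_terms = 60)
#' fit <- chill_fit(obs, g, cond, init = list(alpha = 1e-7, h_reduced = 1e-6),
#'                  n_terms = 60)
#' @export
chill_fit <- function(data, geometry, conditions,
                      init = list(alpha = 1e-7, h_reduced = 1e-6),
                      dimensionless = TRUE, n_terms = 200L, step = 1e-3,
                      lambda0 = 1e-3, max_iter = 100L, rel_tol = 1e-5,
                      rho_cp = NULL, scale_covariance = FALSE) {
  stopifnot(inherits(data, "observation_series"),
            inherits(geometry, "cylinder_geometry"),
            inherits(conditions, "chilling_conditions"))
  if (data$n < 3L) stop("need at least 3 observations", call. = FALSE)
  init <- as.list(init)
  a <- c(init$alpha, init$h_reduced)
  if (length(a) != 2L || any(!is.finite(a)) || any(a <= 0))
    stop("`init` must give positive `alpha` and `h_reduced`", call. = FALSE)

  if (dimensionless && data$scale == "celsius")
    data <- to_dimensionless(data, conditions)

  obj <- function(a) {
    d <- fit_residuals(thermal_parameters(a[1], a[2]), data, geometry,
                       conditions, n_terms)
    list(delta = d, chi2 = sum((d / data$sigmas)^2))
  }

  cur <- obj(a)
  lambda <- lambda0
  history <- data.frame(iter = 0L, alpha = a[1], h_reduced = a[2],
                        chi2 = cur$chi2, lambda = NA_real_)
  converged <- FALSE
  iter <- 0L
  M_last <- NULL
  while (iter < max_iter && !converged) {
    J <- sensitivity_matrix(thermal_parameters(a[1], a[2]), data, geometry,
                            conditions, step, n_terms)
    ne <- normal_equations(J, cur$delta, data$sigmas)
    M_last <- ne$M
    accepted <- FALSE
    for (try in 1:40) {
      Md <- ne$M + lambda * diag(diag(ne$M), 2L)
      dA <- tryCatch(solve(Md, ne$C), error = function(e) NULL)
      if (is.null(dA)) { lambda <- lambda * 10; next }
      # keep parameters positive: halve the step until both stay > 0
      halvings <- 0L
      while (any(a + dA <= 0) && halvings < 60L) {
        dA <- dA / 2
        halvings <- halvings + 1L
      }
      if (any(a + dA <= 0)) { lambda <- lambda * 10; next }
      cand <- obj(a + dA)
      if (cand$chi2 <= cur$chi2) {
        a <- a + dA
        cur <- cand
        lambda <- lambda / 10
        accepted <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    iter <- iter + 1L
    if (!accepted) break  # damping exhausted: chi2 cannot be lowered
    history <- rbind(history,
                     data.frame(iter = iter, alpha = a[1], h_reduced = a[2],
                                chi2 = cur$chi2, lambda = lambda))
    converged <- all(abs(dA / a) < rel_tol)
  }

  a <- unname(a)  # solve() steps attach parameter names

  # covariance from the final undamped normal matrix at the converged point
  J <- sensitivity_matrix(thermal_parameters(a[1], a[2]), data, geometry,
                          conditions, step, n_terms)
  ne <- normal_equations(J, cur$delta, data$sigmas)
  cov_ok <- TRUE
  covariance <- tryCatch(solve(ne$M), error = function(e) {
    cov_ok <<- FALSE
    matrix(NA_real_, 2L, 2L)
  })
  if (cov_ok && scale_covariance && data$n > 2L)
    covariance <- covariance * cur$chi2 / (data$n - 2L)
  dimnames(covariance) <- list(c("alpha", "h_reduced"),
                               c("alpha", "h_reduced"))

  model <- .model_curve(thermal_parameters(a[1], a[2]), data$times, geometry,
                        conditions, data$scale, n_terms)
  stats <- fit_statistics(data$temps, model, data$sigmas)
  rep <- if (cov_ok) covariance_report(covariance = covariance,
                                       rho_cp = rho_cp)
         else list(expanded_uncertainty = c(alpha = NA_real_,
                                            h_reduced = NA_real_),
                   correlation = NA_real_)

  bi <- param_biot(thermal_parameters(a[1], a[2]), geometry)
  out <- list(alpha = a[1], h_reduced = a[2],
              h_H = if (!is.null(rho_cp)) a[2] * rho_cp else NA_real_,
              k = if (!is.null(rho_cp)) a[1] * rho_cp else NA_real_,
              covariance = covariance,
              expanded_uncertainty = rep$expanded_uncertainty,
              correlation = rep$correlation,
              u_h_H = if (!is.null(rho_cp))
                        rep$expanded_uncertainty[["h_reduced"]] * rho_cp
                      else NA_real_,
              bi1 = bi[["bi1"]], bi2 = bi[["bi2"]],
              regime = classify_regime(bi[["bi1"]], bi[["bi2"]]),
              chi2 = stats$chi2, rmse = stats$rmse, r2 = stats$r2,
              sigma_fit = stats$sigma_fit,
              iterations = iter, converged = converged,
              covariance_ok = cov_ok, history = history,
              scale = data$scale, n = data$n, n_terms = n_terms,
              fitted = model, data = data,
              geometry = geometry, conditions = conditions)
  class(out) <- "chill_fit"
  out
}

#' @export
print.chill_fit <- function(x, ...) {
  u <- x$expanded_uncertainty
  cat("Finite-cylinder chilling fit (damped least squares)\n")
  cat(sprintf("  alpha     = %.4e +/- %.2e m^2/s (coverage factor 2)\n",
              x$alpha, u[["alpha"]]))
  cat(sprintf("  h'        = %.4e +/- %.2e m/s\n", x$h_reduced,
              u[["h_reduced"]]))
  if (!is.na(x$h_H))
    cat(sprintf("  h_H       = %.3f +/- %.3f W/(m^2 K)\n", x$h_H, x$u_h_H))
  cat(sprintf("  corr(a,h') = %.4f | Bi1 = %.3f, Bi2 = %.3f (%s)\n",
              x$correlation, x$bi1, x$bi2, x$regime))
  cat(sprintf("  chi2 = %.4e, RMSE = %.4e, R2 = %.4f, sigma_fit = %.4e\n",
              x$chi2, x$rmse, x$r2, x$sigma_fit))
  cat(sprintf("  %d iterations, %sconverged (N = %d, scale = %s)\n",
              x$iterations, if (x$converged) "" else "NOT ", x$n, x$scale))
  invisible(x)
}

#' Covariance-derived uncertainty report
#'
#' From the final normal matrix `M` (or directly from a covariance matrix),
#' computes the covariance \eqn{M^{-1}}, expanded uncertainties
#' \eqn{u_j = 2\sqrt{cov_{jj}}} (coverage factor 2, approximately 95.4%
#' under Gaussian errors) and the parameter correlation
#' \eqn{cov_{12}/\sqrt{cov_{11} cov_{22}}}. When `rho_cp` is supplied the
#' \eqn{h'} uncertainty is also given on the \eqn{h_H} scale.
#'
#' @param M Final 2 x 2 undamped normal matrix (provide this or
#'   `covariance`).
#' @param covariance 2 x 2 covariance matrix in `(alpha, h_reduced)` units.
#' @param rho_cp Optional volumetric heat capacity \eqn{\rho C_p}.
#' @return List with `covariance`, `expanded_uncertainty` (named, factor-2),
#'   `correlation`, and optionally `u_h_H`.
#' @examples
#' cv <- matrix(c(8.2578e-17, -1.8611e-16, -1.8611e-16, 5.2435e-16), 2, 2)
#' covariance_report(covariance = cv)$correlation # -0.8944
#' @export
covariance_report <- function(M = NULL, covariance = NULL, rho_cp = NULL) {
  if (is.null(covariance)) {
    if (is.null(M)) stop("supply `M` or `covariance`", call. = FALSE)
    covariance <- tryCatch(solve(M), error = function(e)
      stop("normal matrix is singular; covariance unavailable",
           call. = FALSE))
  }
  stopifnot(is.matrix(covariance), all(dim(covariance) == 2L))
  if (any(diag(covariance) < 0))
    stop("covariance diagonal must be nonnegative", call. = FALSE)
  u <- 2 * sqrt(diag(covariance))
  names(u) <- c("alpha", "h_reduced")
  corr <- covariance[1, 2] / sqrt(covariance[1, 1] * covariance[2, 2])
  out <- list(covariance = covariance, expanded_uncertainty = u,
              correlation = corr)
  if (!is.null(rho_cp)) out$u_h_H <- u[["h_reduced"]] * rho_cp
  out
}

#' Goodness-of-fit statistics
#'
#' \eqn{\chi^2 = \sum (\delta_i/\sigma_i)^2},
#' \eqn{RMSE = \sqrt{\sum \delta_i^2 / N}},
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}},
#' \eqn{\sigma_{fit} = \sqrt{\sum \delta_i^2 / (N - 2)}} (two fitted
#' parameters).
#'
#' @param observed Observed values.
#' @param model Simulated values, same length.
#' @param sigmas Measurement uncertainties (scalar or vector), default 1.
#' @return List with `chi2`, `rmse`, `r2`, `sigma_fit`.
#' @examples
#' fit_statistics(c(1, 0.5, 0.25), c(1, 0.4, 0.35))
#' @export
fit_statistics <- function(observed, model, sigmas = 1) {
  n <- length(observed)
  stopifnot(length(model) == n)
  if (n <= 2L)
    stop("sigma_fit is undefined for N <= 2 (two fitted parameters)",
         call. = FALSE)
  delta <- observed - model
  ss_res <- sum(delta^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(chi2 = sum((delta / sigmas)^2),
       rmse = sqrt(ss_res / n),
       r2 = 1 - ss_res / ss_tot,
       sigma_fit = sqrt(ss_res / (n - 2)))
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, uncertainties, covariance, correlation, Biot numbers,
#' regime, fit statistics and the iteration history.
#'
#' @param fit A `chill_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "chill_fit"))
  rpt <- list(
    parameters = list(alpha = fit$alpha, h_reduced = fit$h_reduced,
                      h_H = fit$h_H, k = fit$k),
    expanded_uncertainty = as.list(fit$expanded_uncertainty),
    u_h_H = fit$u_h_H,
    covariance = unname(fit$covariance),
    correlation = fit$correlation,
    biot = list(bi1 = fit$bi1, bi2 = fit$bi2, regime = fit$regime),
    statistics = list(chi2 = fit$chi2, rmse = fit$rmse, r2 = fit$r2,
                      sigma_fit = fit$sigma_fit),
    iterations = fit$iterations, converged = fit$converged,
    n = fit$n, scale = fit$scale, n_terms = fit$n_terms,
    history = fit$history)
  jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
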