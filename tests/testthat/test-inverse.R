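test_that("residuals vanish on self-generated data and are linear in the data", {
  g <- ref_geometry(); cond <- ref_conditions(); p <- ref_params()
  obs <- generate_observations(carrot_design(), n_terms = 80)
  expect_equal(obs$n, 49L)
  d <- fit_residuals(p, to_dimensionless(obs, cond), g, cond, n_terms = 80)
  expect_length(d, 49L)
  expect_lt(max(abs(d)), 1e-10)
  shifted <- observation_series(obs$times, obs$temps + 0.7, obs$sigmas)
  d2 <- fit_residuals(p, shifted, g, cond, n_terms = 80)
  expect_equal(d2, rep(0.7, 49), tolerance = 1e-9)
})

test_that("sensitivities: alpha column nonpositive, second-order in step, zero at t = 0", {
  g <- ref_geometry(); cond <- ref_conditions(); p <- ref_params()
  obs <- to_dimensionless(generate_observations(carrot_design(), 80), cond)
  J <- sensitivity_matrix(p, obs, g, cond, step = 1e-3, n_terms = 80)
  late <- obs$times > 0
  expect_true(all(J[late, "alpha"] <= 0))
  # at t = 0 only the tiny truncation residue of the initial condition
  # responds to the parameters: relative to the peak sensitivity it is noise
  for (j in 1:2)
    expect_lt(abs(J[1, j]) / max(abs(J[, j])), 5e-3)
  # halving the step barely moves the entries (second-order accuracy),
  # measured against each column's scale
  J2 <- sensitivity_matrix(p, obs, g, cond, step = 5e-4, n_terms = 80)
  for (j in 1:2)
    expect_lt(max(abs(J[, j] - J2[, j])) / max(abs(J[, j])), 1e-4)
})

test_that("normal equations have the stated structure and scale invariance", {
  J <- cbind(c(1, 0, 1, 0), c(0, 1, 0, -1))  # orthogonal columns
  ne <- normal_equations(J, rep(0, 4))
  expect_equal(ne$M[1, 2], 0)
  expect_equal(ne$C, c(0, 0))
  delta <- c(0.1, -0.2, 0.05, 0.3)
  ne1 <- normal_equations(J, delta, sigmas = 1)
  ne2 <- normal_equations(J, delta, sigmas = 2)
  expect_equal(ne2$M, ne1$M / 4)
  expect_equal(ne2$C, ne1$C / 4)
  expect_equal(solve(ne1$M, ne1$C), solve(ne2$M, ne2$C))
})

test_that("starting at the truth converges immediately with zero chi-square", {
  g <- ref_geometry(); cond <- ref_conditions()
  d <- carrot_design()
  obs <- generate_observations(d, n_terms = 60)
  fit <- chill_fit(obs, g, cond,
                   init = list(alpha = d$truth$alpha,
                               h_reduced = d$truth$h_reduced),
                   n_terms = 60)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_lt(fit$chi2, 1e-15)
})

test_that("noiseless recovery across a grid of diffusivities and Biot numbers", {
  g <- ref_geometry(); cond <- ref_conditions()
  rho_cp <- ref_rho_cp()
  for (alpha in c(1e-7, 1.5e-7, 2e-7)) {
    for (bi1 in c(0.15, 0.3, 1, 5)) {
      truth <- thermal_parameters(alpha, bi1 * alpha / g$radius)
      des <- synth_design(g, cond, truth,
                          times = seq(0, 3600, length.out = 49))
      obs <- generate_observations(des, n_terms = 60)
      fit <- chill_fit(obs, g, cond,
                       init = list(alpha = 1e-7, h_reduced = 4 / rho_cp),
                       n_terms = 60)
      lab <- sprintf("alpha = %g, Bi1 = %g", alpha, bi1)
      expect_true(fit$converged, label = paste("converged at", lab))
      expect_lt(abs(fit$alpha - alpha) / alpha, 1e-3, label = lab)
      expect_lt(abs(fit$h_reduced - truth$h_reduced) / truth$h_reduced, 1e-3,
                label = lab)
    }
  }
})

test_that("chi-square is nonincreasing over accepted iterations and correlation is negative", {
  g <- ref_geometry(); cond <- ref_conditions()
  obs <- generate_observations(carrot_design(noise_sd = 0.005, seed = 11), 60)
  fit <- chill_fit(obs, g, cond,
                   init = list(alpha = 1e-7, h_reduced = 4 / ref_rho_cp()),
                   n_terms = 60, rho_cp = ref_rho_cp())
  expect_true(all(diff(fit$history$chi2) <= 0))
  expect_lt(fit$correlation, 0)
  expect_true(abs(fit$correlation) <= 1)
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(diag(fit$covariance) >= 0))
  expect_equal(fit$h_H, fit$h_reduced * ref_rho_cp())
})

test_that("estimates agree with an independent Levenberg-Marquardt implementation", {
  skip_if_not_installed("minpack.lm")
  g <- ref_geometry(); cond <- ref_conditions()
  obs <- generate_observations(carrot_design(noise_sd = 0.005, seed = 3), 60)
  star <- to_dimensionless(obs, cond)
  fit <- chill_fit(obs, g, cond,
                   init = list(alpha = 1e-7, h_reduced = 4 / ref_rho_cp()),
                   n_terms = 60)
  resid_fn <- function(par) {
    p <- thermal_parameters(par[1], par[2])
    (star$temps - center_curve(star$times, g, p, 60)) / star$sigmas
  }
  ext <- minpack.lm::nls.lm(par = c(1e-7, 4 / ref_rho_cp()), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_lt(abs(fit$alpha - ext$par[1]) / ext$par[1], 1e-3)
  expect_lt(abs(fit$h_reduced - ext$par[2]) / ext$par[2], 1e-3)
})

test_that("covariance report reproduces the reference matrix summary", {
  cv <- matrix(c(8.2578e-17, -1.8611e-16, -1.8611e-16, 5.2435e-16), 2, 2)
  rep <- covariance_report(covariance = cv, rho_cp = ref_rho_cp())
  expect_equal(round(rep$correlation, 4), -0.8944)
  expect_equal(round(rep$expanded_uncertainty[["alpha"]] * 1e7, 2), 0.18)
  # the h' uncertainty mapped to the h_H scale
  expect_equal(rep$u_h_H, 2 * sqrt(cv[2, 2]) * ref_rho_cp())
  rep_id <- covariance_report(covariance = diag(2))
  expect_equal(rep_id$correlation, 0)
  expect_equal(unname(rep_id$expanded_uncertainty), c(2, 2))
  # report from a normal matrix inverts it
  M <- solve(cv)
  expect_equal(covariance_report(M = M)$covariance, cv, tolerance = 1e-10)
})

test_that("fit statistics definitions", {
  perfect <- fit_statistics(c(1, 0.5, 0.25), c(1, 0.5, 0.25))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$sigma_fit, 0)
  toy <- fit_statistics(c(1, 0.5, 0.25), c(1, 0.4, 0.35))
  expect_equal(toy$chi2, 0.02)
  expect_equal(toy$rmse, sqrt(0.02 / 3))
  expect_equal(toy$sigma_fit, sqrt(0.02 / 1))
  # homogeneity: scaling residuals by c scales chi2 by c^2 and rmse by c
  toy2 <- fit_statistics(c(1, 0.5, 0.25), c(1, 0.3, 0.45))
  expect_equal(toy2$chi2, 4 * toy$chi2)
  expect_equal(toy2$rmse, 2 * toy$rmse)
  expect_error(fit_statistics(c(1, 2), c(1, 2)), "N <= 2")
})

test_that("fit fails loudly on bad inputs and records non-convergence", {
  g <- ref_geometry(); cond <- ref_conditions()
  obs <- generate_observations(carrot_design(), 40)
  expect_error(chill_fit(obs, g, cond, init = list(alpha = -1, h_reduced = 1)),
               "positive")
  two <- observation_series(c(0, 60), c(19.9, 18), 1)
  expect_error(chill_fit(two, g, cond), "at least 3")
  fit <- chill_fit(obs, g, cond,
                   init = list(alpha = 1e-7, h_reduced = 4 / ref_rho_cp()),
                   n_terms = 40, max_iter = 1L)
  expect_false(fit$converged)
})
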