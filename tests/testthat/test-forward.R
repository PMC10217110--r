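test_that("truncated series honours the initial condition and equilibrium", {
  g <- ref_geometry(); p <- ref_params()
  expect_lt(abs(dimensionless_temperature(0, 0, 0, g, p, 200) - 1), 1e-2)
  expect_lt(abs(dimensionless_temperature(0.011, 0.01, 0, g, p, 200) - 1),
            1e-2)
  expect_lt(abs(dimensionless_temperature(0, 0, 1e7, g, p, 200)), 1e-12)
})

test_that("the interior lags the boundary at intermediate times", {
  g <- ref_geometry(); p <- ref_params()
  t_mid <- 900
  expect_gt(dimensionless_temperature(0, 0, t_mid, g, p, 100),
            dimensionless_temperature(0.011, 0.010, t_mid, g, p, 100))
})

test_that("temperature is the affine map of the dimensionless solution", {
  g <- ref_geometry(); p <- ref_params(); cond <- ref_conditions()
  ts <- dimensionless_temperature(0, 0, c(0, 600, 3600), g, p, 100)
  tc <- temperature(0, 0, c(0, 600, 3600), g, p, cond, 100)
  expect_equal(tc, 3.5 + (19.9 - 3.5) * ts, tolerance = 1e-12)
  # round trip back to dimensionless
  expect_equal((tc - cond$teq) / (cond$t0 - cond$teq), ts, tolerance = 1e-12)
})

test_that("centre curve decreases after the truncation plateau and scales as 1/alpha", {
  g <- ref_geometry(); p <- ref_params()
  tt <- seq(60, 3600, by = 60)
  curve <- center_curve(tt, g, p, 100)
  expect_true(all(diff(curve) < 0))
  # doubling alpha at fixed Biot numbers (h' doubled too) halves the clock
  p2 <- thermal_parameters(2 * p$alpha, 2 * p$h_reduced)
  expect_equal(center_curve(tt, g, p2, 100), center_curve(2 * tt, g, p, 100),
               tolerance = 1e-12)
})

test_that("field is y-symmetric, consistent with point evaluation, and radially nonincreasing", {
  g <- ref_geometry(); p <- ref_params()
  r <- seq(0, g$radius, length.out = 9)
  y <- seq(-g$length / 2, g$length / 2, length.out = 7)
  f <- temperature_field(r, y, 780, g, p, 100)
  expect_equal(f$values, f$values[, rev(seq_along(y))], tolerance = 1e-12)
  expect_equal(f$values[3, 2],
               dimensionless_temperature(r[3], y[2], 780, g, p, 100),
               tolerance = 1e-12)
  # chilling front advances inward: centre row nonincreasing in r
  mid <- which(y == 0)
  expect_true(all(diff(f$values[, mid]) < 0))
  # long format export carries the full grid
  df <- as.data.frame(f)
  expect_equal(nrow(df), length(r) * length(y))
  expect_equal(df$T_star[1], f$values[1, 1])
})

test_that("centre solution equals an explicit nested double sum", {
  g <- ref_geometry()
  bi <- 0.5  # equal Biot numbers on both sub-problems
  alpha <- 1.4e-7
  h_red <- bi * alpha / g$radius
  p <- thermal_parameters(alpha, h_red)
  # geometry with L/2 = R so both Biot numbers equal bi
  g_eq <- cylinder_geometry(g$radius, 2 * g$radius)
  for (t in c(120, 600, 1800)) {
    expect_equal(dimensionless_temperature(0, 0, t, g_eq, p, 40),
                 double_sum_center(bi, bi, g_eq, alpha, t, 40),
                 tolerance = 1e-10)
  }
})

test_that("third-kind solution at huge Biot matches the first-kind solution", {
  g <- ref_geometry()
  alpha <- 1.43e-7
  h_red <- 1e6 * alpha / g$radius  # Bi1 = 1e6
  p <- thermal_parameters(alpha, h_red)
  fk_c <- first_kind_coefficients("cylinder", 100)
  fk_w <- first_kind_coefficients("wall", 100)
  R <- g$radius; Lh <- g$length / 2
  for (t in c(300, 900, 1800)) {
    want <- sum(fk_c$coeffs * exp(-fk_c$roots^2 / R^2 * alpha * t)) *
      sum(fk_w$coeffs * exp(-fk_w$roots^2 / Lh^2 * alpha * t))
    expect_equal(dimensionless_temperature(0, 0, t, g, p, 100), want,
                 tolerance = 1e-4)
  }
})

test_that("centre-surface gap: lumped limit is tiny and the scan is dt-stable", {
  g <- ref_geometry()
  # Bi ~ 1e-3: nearly uniform internal temperature
  p_lump <- thermal_parameters(1.43e-7, 1e-3 * 1.43e-7 / g$radius)
  res <- max_center_surface_gap(g, p_lump, t_max = 3600, dt = 30,
                                n_terms = 60)
  expect_lt(res$gap, 0.01)
  p <- ref_params()
  g10 <- max_center_surface_gap(g, p, t_max = 3600, dt = 10, n_terms = 100)
  g1 <- max_center_surface_gap(g, p, t_max = 3600, dt = 1, n_terms = 100)
  expect_lt(abs(g10$gap - g1$gap), 1e-3)
})

test_that("solution stays in [0, 1] past the truncation plateau", {
  g <- ref_geometry()
  for (bi in c(0.1, 40)) {
    p <- thermal_parameters(1.43e-7, bi * 1.43e-7 / g$radius)
    for (t in c(60, 600, 3600)) {
      f <- temperature_field(seq(0, g$radius, length.out = 6),
                             seq(0, g$length / 2, length.out = 5), t, g, p,
                             100)
      expect_true(all(f$values >= -1e-6 & f$values <= 1 + 1e-6),
                  label = sprintf("bounds at Bi = %g, t = %g", bi, t))
    }
  }
})

test_that("volume-averaged temperature is nonincreasing in time", {
  g <- ref_geometry(); p <- ref_params()
  r <- seq(0, g$radius, length.out = 25)
  y <- seq(-g$length / 2, g$length / 2, length.out = 21)
  vol_avg <- function(t) {
    f <- temperature_field(r, y, t, g, p, 80)
    w <- f$values * r  # cylindrical volume element ~ r dr dy
    # trapezoid in both directions
    ry <- apply(w, 2, function(col) sum(diff(r) * (head(col, -1) + tail(col, -1)) / 2))
    sum(diff(y) * (head(ry, -1) + tail(ry, -1)) / 2)
  }
  avgs <- vapply(seq(60, 3600, by = 300), vol_avg, numeric(1))
  expect_true(all(diff(avgs) < 0))
})

test_that("regime classification follows the 0.1 and 40 thresholds", {
  expect_identical(classify_regime(0.271, 0.246), "third_kind")
  expect_identical(classify_regime(0.05, 0.05), "lumped")
  expect_identical(classify_regime(100, 50), "first_kind")
  expect_identical(classify_regime(100, 0.05), "third_kind")  # mixed
  expect_error(classify_regime(-1, 1), ">= 0")
})

test_that("domain errors: point outside cylinder, negative time", {
  g <- ref_geometry(); p <- ref_params()
  expect_error(dimensionless_temperature(0.03, 0, 10, g, p, 20), "radial")
  expect_error(dimensionless_temperature(0, 0.021, 10, g, p, 20), "axial")
  expect_error(dimensionless_temperature(0, 0, -1, g, p, 20), "negative")
})
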