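# Shared fixtures and independent oracles for the test suite.

# Reference study conditions: cylindrical carrot piece chilled from 19.9 to
# 3.5 C; fitted alpha = 1.43e-7 m^2/s, h_H = 6.92 W/(m^2 K), rho*Cp from
# 1003 kg/m^3 and 3918 J/(kg K).
ref_geometry <- function() cylinder_geometry(radius = 0.022, length = 0.040)
ref_conditions <- function() chilling_conditions(t0 = 19.9, teq = 3.5)
ref_rho_cp <- function() 1003 * 3918
ref_params <- function() thermal_parameters(alpha = 1.43e-7,
                                            h_reduced = 6.92 / ref_rho_cp())

# Independent eigenvalue oracle: dense sign-change scan of the
# characteristic residual on a fine grid, refined by uniroot. Slow but
# makes no use of the package's bracketing strategy.
oracle_roots <- function(kind, biot, n, step = 1e-4) {
  f <- if (kind == "cylinder") {
    function(mu) mu * besselJ(mu, 1) - biot * besselJ(mu, 0)
  } else {
    function(mu) mu * sin(mu) - biot * cos(mu)
  }
  upper <- (n + 2) * pi
  grid <- seq(step, upper, by = step)
  fg <- f(grid)
  sign_change <- which(fg[-1] * fg[-length(fg)] <= 0)
  roots <- numeric(0)
  for (i in sign_change) {
    roots <- c(roots, uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)$root)
    if (length(roots) >= n) break
  }
  stopifnot(length(roots) >= n)
  roots[seq_len(n)]
}

# Independent Bessel J1 via its power series (converges fast for the
# moderate arguments used in tests).
series_j1 <- function(x, k_max = 40L) {
  k <- 0:k_max
  sum((-1)^k / (factorial(k) * factorial(k + 1)) * (x / 2)^(2 * k + 1))
}

# Explicit nested double-sum evaluation of the centre solution; deliberately
# ignores the factorisation the implementation relies on.
double_sum_center <- function(bi1, bi2, geometry, alpha, t, n_terms) {
  mun <- find_roots("cylinder", bi1, n_terms)
  An <- third_kind_coefficients("cylinder", mun, bi1)
  mum <- find_roots("wall", bi2, n_terms)
  Am <- third_kind_coefficients("wall", mum, bi2)
  R <- geometry$radius; Lh <- geometry$length / 2
  acc <- 0
  for (n in seq_len(n_terms))
    for (m in seq_len(n_terms))
      acc <- acc + An[n] * Am[m] *
        exp(-(mun[n]^2 / R^2 + mum[m]^2 / Lh^2) * alpha * t)
  acc
}
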