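# Eigenproblem of the separated finite-cylinder conduction solution.
#
# Radial sub-problem (infinite cylinder), third-kind boundary:
#   mu * J1(mu) = Bi1 * J0(mu)
# Axial sub-problem (infinite wall):
#   mu * sin(mu) = Bi2 * cos(mu)   (i.e. cot mu = mu/Bi2)
# Roots are bracketed analytically (interlaced Bessel zeros for the
# cylinder, ((m-1)pi, (m-1)pi + pi/2) for the wall) so bisection is
# guaranteed one sign change per bracket at any Bi > 0.

# Biot at or above this value is treated as infinite (first-kind limit).
.BIOT_INFINITE <- 1e8

#' Zeros of the Bessel functions J0 and J1
#'
#' First `n` positive zeros of \eqn{J_\nu} for \eqn{\nu \in \{0, 1\}},
#' computed by bisection from McMahon asymptotic brackets.
#'
#' @param nu Order, 0 or 1.
#' @param n Number of zeros.
#' @param tol Bracket-width stopping tolerance.
#' @return Numeric vector of length `n`, strictly increasing.
#' @examples
#' bessel_zeros(0, 3) # 2.404826, 5.520078, 8.653728
#' @export
bessel_zeros <- function(nu, n, tol = 1e-13) {
  stopifnot(nu %in% c(0, 1), n >= 1)
  k <- seq_len(n)
  beta <- (k + nu / 2 - 0.25) * pi
  approx <- beta - (4 * nu^2 - 1) / (8 * beta)
  .bisect_vec(function(x) besselJ(x, nu), approx - 0.4, approx + 0.4, tol,
              what = sprintf("zero of J%d", nu))
}

# Vectorized bisection on pre-validated brackets; errors name the first
# bracket whose endpoints do not straddle a sign change.
.bisect_vec <- function(f, lo, hi, tol, what = "root") {
  flo <- f(lo); fhi <- f(hi)
  bad <- which(flo * fhi > 0)
  if (length(bad))
    stop(sprintf("bisection bracket failure for %s index %d: no sign change in [%g, %g]",
                 what, bad[1L], lo[bad[1L]], hi[bad[1L]]), call. = FALSE)
  it <- 0L
  while (max(hi - lo) > tol && it < 200L) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    down <- flo * fm <= 0            # root in [lo, mid]
    hi[down] <- mid[down]
    lo[!down] <- mid[!down]
    flo[!down] <- fm[!down]
    it <- it + 1L
  }
  (lo + hi) / 2
}

# Characteristic residual functions; a valid eigenvalue makes these zero.
.char_residual <- function(kind, mu, biot) {
  if (kind == "cylinder") mu * besselJ(mu, 1) - biot * besselJ(mu, 0)
  else                    mu * sin(mu) - biot * cos(mu)
}

.check_kind <- function(kind) match.arg(kind, c("cylinder", "wall"))

.check_biot <- function(biot) {
  if (identical(biot, "infinite")) return(Inf)
  stopifnot(is.numeric(biot), length(biot) == 1L)
  if (is.nan(biot) || biot < 0)
    stop("Biot number must be >= 0 (or infinite)", call. = FALSE)
  if (biot >= .BIOT_INFINITE) return(Inf)
  biot
}

#' Eigenvalues of the characteristic equations
#'
#' Solves \eqn{\mu J_1(\mu) = Bi\, J_0(\mu)} (`kind = "cylinder"`) or
#' \eqn{\mu \sin\mu = Bi \cos\mu} (`kind = "wall"`) for the first
#' `n_roots` positive roots by bisection. `biot = Inf` (or the string
#' `"infinite"`) gives the first-kind limits: zeros of \eqn{J_0}, and odd
#' multiples of \eqn{\pi/2}.
#'
#' Cylinder roots are bracketed between the interlaced zeros of \eqn{J_1}
#' and \eqn{J_0}; wall root \eqn{m} is bracketed in
#' \eqn{((m-1)\pi, (m-1)\pi + \pi/2)}.
#'
#' @param kind `"cylinder"` or `"wall"`.
#' @param biot Biot number, > 0, or `Inf`/`"infinite"`.
#' @param n_roots Number of roots (default 200).
#' @param tol Bisection bracket-width tolerance (default 1e-12).
#' @return Strictly increasing numeric vector of length `n_roots`.
#' @examples
#' find_roots("cylinder", Inf, 1)        # 2.404826
#' find_roots("wall", 0.246, 3)
#' @export
find_roots <- function(kind = c("cylinder", "wall"), biot, n_roots = 200L,
                       tol = 1e-12) {
  kind <- .check_kind(kind)
  biot <- .check_biot(biot)
  stopifnot(n_roots >= 1, tol > 0)
  n_roots <- as.integer(n_roots)
  if (is.infinite(biot)) {
    return(if (kind == "cylinder") bessel_zeros(0, n_roots, tol)
           else (seq_len(n_roots) - 0.5) * pi)
  }
  if (biot == 0)
    stop("Biot = 0 degenerates the third-kind eigenproblem (no surface ",
         "heat exchange); use a strictly positive Biot number", call. = FALSE)
  if (kind == "cylinder") {
    # root n lies in (j_{1,n-1}, j_{0,n}) with j_{1,0} = 0
    hi <- bessel_zeros(0, n_roots, tol)
    lo <- if (n_roots == 1L) 0 else c(0, bessel_zeros(1, n_roots - 1L, tol))
  } else {
    m <- seq_len(n_roots)
    lo <- (m - 1) * pi
    hi <- (m - 1) * pi + pi / 2
  }
  .bisect_vec(function(mu) .char_residual(kind, mu, biot), lo, hi, tol,
              what = sprintf("%s eigenvalue", kind))
}

#' Series coefficients for the third-kind (convective) boundary
#'
#' Centre-normalised expansion coefficients of the two sub-problems:
#' \deqn{A_n = \frac{2 Bi_1}{J_0(\mu_n)\,(Bi_1^2 + \mu_n^2)}}
#' for the infinite cylinder and
#' \deqn{A_m = (-1)^{m+1}\frac{2 Bi_2 \sqrt{Bi_2^2 + \mu_m^2}}
#'   {\mu_m (Bi_2^2 + Bi_2 + \mu_m^2)}}
#' for the infinite wall (sign alternation from the cosine half-waves).
#' The supplied roots are checked against the characteristic equation and a
#' consistency error is raised if they do not belong to this Biot number.
#'
#' @param kind `"cylinder"` or `"wall"`.
#' @param roots Eigenvalues from [find_roots()] for the same `(kind, biot)`.
#' @param biot Biot number used to obtain `roots`.
#' @param check_tol Tolerance on the characteristic residual (default 1e-8).
#' @return Numeric vector of coefficients, same length as `roots`.
#' @examples
#' mu <- find_roots("cylinder", 0.271, 5)
#' third_kind_coefficients("cylinder", mu, 0.271)
#' @export
third_kind_coefficients <- function(kind = c("cylinder", "wall"), roots, biot,
                                    check_tol = 1e-8) {
  kind <- .check_kind(kind)
  biot <- .check_biot(biot)
  if (is.infinite(biot))
    return(first_kind_coefficients(kind, length(roots))$coeffs)
  if (biot == 0) stop("Biot must be > 0", call. = FALSE)
  # the residual scales with Bi (and mu), so the tolerance must too
  res <- .char_residual(kind, roots, biot)
  if (any(abs(res) > check_tol * (1 + abs(roots)) * (1 + biot)))
    stop("roots are inconsistent with this Biot number (characteristic ",
         "residual above tolerance)", call. = FALSE)
  if (kind == "cylinder") {
    2 * biot / (besselJ(roots, 0) * (biot^2 + roots^2))
  } else {
    m <- seq_along(roots)
    (-1)^(m + 1) * 2 * biot * sqrt(biot^2 + roots^2) /
      (roots * (biot^2 + biot + roots^2))
  }
}

#' Roots and coefficients in the first-kind (prescribed surface) limit
#'
#' For \eqn{Bi \to \infty} the characteristic equations reduce to
#' \eqn{J_0(\mu) = 0} and \eqn{\cot\mu = 0}; the coefficients are
#' \eqn{A_n = 2/(\mu_n J_1(\mu_n))} and
#' \eqn{A_m = (-1)^{m+1} 2/\mu_m}.
#'
#' @param kind `"cylinder"` or `"wall"`.
#' @param n_terms Number of terms, >= 1.
#' @return List with `roots` and `coeffs`, each of length `n_terms`.
#' @examples
#' first_kind_coefficients("wall", 2) # roots pi/2, 3*pi/2; coeffs 4/pi, -4/(3*pi)
#' @export
first_kind_coefficients <- function(kind = c("cylinder", "wall"), n_terms) {
  kind <- .check_kind(kind)
  stopifnot(n_terms >= 1)
  n_terms <- as.integer(n_terms)
  if (kind == "cylinder") {
    mu <- bessel_zeros(0, n_terms)
    list(roots = mu, coeffs = 2 / (mu * besselJ(mu, 1)))
  } else {
    m <- seq_len(n_terms)
    mu <- (m - 0.5) * pi
    list(roots = mu, coeffs = (-1)^(m + 1) * 2 / mu)
  }
}

#' Eigenvalue/coefficient expansion for one sub-problem
#'
#' Bundles [find_roots()] and the matching coefficients into a single
#' object; `biot = Inf` (or >= 1e8) switches to the first-kind limit.
#'
#' @inheritParams find_roots
#' @param n_terms Number of series terms.
#' @return Object of class `eigen_expansion` with fields `kind`, `biot`,
#'   `roots`, `coeffs`, `n_terms`.
#' @examples
#' eigen_expansion("wall", 0.246, n_terms = 10)
#' @export
eigen_expansion <- function(kind = c("cylinder", "wall"), biot,
                            n_terms = 200L, tol = 1e-12) {
  kind <- .check_kind(kind)
  biot <- .check_biot(biot)
  n_terms <- as.integer(n_terms)
  if (is.infinite(biot)) {
    fk <- first_kind_coefficients(kind, n_terms)
    roots <- fk$roots; coeffs <- fk$coeffs
  } else {
    roots <- find_roots(kind, biot, n_terms, tol)
    coeffs <- third_kind_coefficients(kind, roots, biot)
  }
  structure(list(kind = kind, biot = biot, roots = roots, coeffs = coeffs,
                 n_terms = n_terms),
            class = "eigen_expansion")
}

#' @export
print.eigen_expansion <- function(x, ...) {
  cat(sprintf("<eigen_expansion> %s, Bi = %s, %d terms; mu1 = %.6f, A1 = %.6f\n",
              x$kind, format(x$biot), x$n_terms, x$roots[1L], x$coeffs[1L]))
  invisible(x)
}

# Memoised expansions keyed by (kind, biot, n_terms, tol); the inverse solver
# re-evaluates the forward model at many nearby Biot numbers, so the cache is
# bounded and evicted wholesale when full.
.eigen_cache <- new.env(parent = emptyenv())

.cached_expansion <- function(kind, biot, n_terms, tol = 1e-12) {
  key <- paste(kind, format(biot, digits = 17), n_terms, format(tol), sep = "|")
  hit <- .eigen_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- eigen_expansion(kind, biot, n_terms, tol)
  if (length(ls(.eigen_cache)) > 512L)
    rm(list = ls(.eigen_cache), envir = .eigen_cache)
  assign(key, val, envir = .eigen_cache)
  val
}
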