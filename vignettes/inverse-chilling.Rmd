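---
title: "Inverse estimation of thermal properties from a chilling curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse estimation of thermal properties from a chilling curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillfit)
```

## The forward model and its assumptions

`chillfit` models the chilling of a solid finite cylinder (radius $R$,
length $L$, origin at the geometric centre) by conduction,

$$\frac{\partial T}{\partial t} = \alpha \left[ \frac{1}{r}
\frac{\partial}{\partial r}\left(r \frac{\partial T}{\partial r}\right) +
\frac{\partial^2 T}{\partial y^2} \right],$$

under seven assumptions: no internal heat generation; a known uniform
initial temperature $T_0$; homogeneous isotropic material; constant
thermophysical properties (defensible for chilling, where the temperature
span is under 20 °C); radial and axial symmetry; a constant coolant
temperature $T_{eq}$; and a convective third-kind boundary,
$-k\,\partial T/\partial n = h_H (T_{surf} - T_{eq})$, with the same $h_H$
on the lateral surface and both end faces. Separation of variables then
gives the product-form series for the dimensionless temperature
$T^* = (T - T_{eq})/(T_0 - T_{eq})$ shown in the README: a Bessel $J_0$
expansion in $r$ times a cosine expansion in $y$.

Because the rectangularly truncated double series factorises exactly into
the product of the two one-dimensional partial sums, the implementation
evaluates the two sub-problem sums separately and multiplies them. A unit
test verifies this against a deliberately naive nested double sum.

### The eigenproblem

The radial eigenvalues solve $\mu J_1(\mu) = Bi_1 J_0(\mu)$ with
$Bi_1 = h_H R/k$; the axial ones solve $\mu\sin\mu = Bi_2\cos\mu$ with
$Bi_2 = h_H (L/2)/k$. Both are solved by bisection with a bracket-width
tolerance of $10^{-12}$ and analytically guaranteed brackets:

* cylinder root $n$ lies strictly between the interlaced zeros
  $j_{1,n-1}$ of $J_1$ (with $j_{1,0} = 0$) and $j_{0,n}$ of $J_0$; the
  Bessel zeros themselves come from bisection started at McMahon
  asymptotic brackets;
* wall root $m$ lies in $((m-1)\pi,\,(m-1)\pi + \pi/2)$.

With one sign change per bracket, bisection cannot skip or duplicate a
root at any Biot number. The centre-normalised coefficients are

$$A_n = \frac{2\,Bi_1}{J_0(\mu_n)\,(Bi_1^2 + \mu_n^2)}, \qquad
A_m = (-1)^{m+1} \frac{2\,Bi_2\sqrt{Bi_2^2 + \mu_m^2}}
{\mu_m\,(Bi_2^2 + Bi_2 + \mu_m^2)},$$

algebraically equivalent (via the eigencondition) to the textbook forms
$2J_1(\mu)/[\mu(J_0^2+J_1^2)]$ and $2\sin\mu/(\mu + \sin\mu\cos\mu)$; the
tests assert this equivalence to $10^{-10}$. In the limit
$Bi \to \infty$ the equations degenerate to $J_0(\mu) = 0$ and
$\cot\mu = 0$ with coefficients $2/(\mu_n J_1(\mu_n))$ and
$(-1)^{m+1}2/\mu_m$; the package switches to these closed forms for
$Bi \ge 10^8$. $Bi = 0$ is rejected: the eigenproblem degenerates and
physically nothing cools.

### Truncation

The default is 200 terms per sub-problem. Convergence is fastest at small
Biot and late time; the slowest case is $t = 0$, where the truncated
series reproduces the initial condition $T^* = 1$ only to about
$2\times10^{-5}$ at $Bi \approx 0.25$ and to a few $10^{-3}$ at $Bi = 40$
(the coefficient tails decay slowly as the first-kind limit is
approached). `dimensionless_temperature()` returns the truncated value at
$t = 0$ rather than clamping it to 1, keeping the function a pure series
evaluator; tests therefore allow a $10^{-2}$ truncation band at $t = 0$.
For $t$ beyond about one minute at the study conditions the truncation
error is far below $10^{-12}$.

## The inverse estimator

The centre curve depends on exactly two parameters: $\alpha$ and the
reduced coefficient $h' = h_H/(\rho C_p)$ (units m/s), since
$Bi_1 = h'R/\alpha$ and $Bi_2 = h'(L/2)/\alpha$. Fitting is done on the
dimensionless scale by default — the data is transformed with
$T^*_i = (T_i - T_{eq})/(T_0 - T_{eq})$ and known uncertainties scaled by
$1/|T_0 - T_{eq}|$ — with unit weights when uncertainties are unknown
(the conventional all-ones third column of the input file). A flag allows
fitting raw °C instead.

Each iteration builds the weighted normal equations
$M\,\Delta A = C$ with $M_{jk} = \sum_i J_{ij}J_{ik}/\sigma_i^2$ and
$C_j = \sum_i \delta_i J_{ij}/\sigma_i^2$, where
$\delta_i = T_i^{obs} - T_i^{sim}$ and $J$ holds central
finite-difference sensitivities with relative step $10^{-3}$ (halving the
step changes entries by under $10^{-4}$ of the column scale, confirming
second-order accuracy; the step size is therefore uncritical).
Levenberg damping stabilises the Gauss–Newton step:
$(M + \lambda\,\mathrm{diag}\,M)\Delta A = C$ with $\lambda_0 = 10^{-3}$,
divided by 10 after an accepted step (one that does not increase
$\chi^2 = \sum\delta_i^2/\sigma_i^2$) and multiplied by 10 otherwise.
Undamped Gauss–Newton can diverge from distant starting values such as
$\alpha_0 = 10^{-7}$ m²/s; damping makes the start routine. Steps that
would drive a parameter non-positive are halved until both stay positive.
Convergence requires both relative corrections
$|\Delta a_j/a_j| < 10^{-5}$; the iteration cap is 100, and
non-convergence is reported in the result rather than raised.

### Uncertainties

The covariance is the plain inverse of the final *undamped* normal matrix
$M^{-1}$, not rescaled by reduced $\chi^2$ (an optional flag enables the
rescaling). Expanded uncertainties use coverage factor 2 (≈95.4 % under
Gaussian errors); the parameter correlation
$\mathrm{cov}_{12}/\sqrt{\mathrm{cov}_{11}\mathrm{cov}_{22}}$ is strongly
negative for centre-point designs — a higher diffusivity can be traded
against a lower surface conductance over much of the curve — which is why
both numbers must be quoted with their covariance. When $\rho C_p$ is
supplied, $h'$ and its uncertainty are also reported on the $h_H$ scale.

Monte-Carlo calibration (part of the test suite) checks the whole chain:
with known Gaussian noise of sd 0.005 on the dimensionless scale, the
factor-2 interval for $\alpha$ covers the truth in 90–99 % of 200
replicate fits of the 49-point reference design. The replicates use 60
series terms — at $Bi \approx 0.25$ the series has converged far below
the noise floor well before 60 terms, and generator and fit share the
same truncation — which keeps the calibration fast without affecting it.

## Property correlations

For high-moisture produce the package provides the affine moisture
correlations $C_p = 1382 + 2805\,X_{wb}/100$ (Fikiin),
$\alpha = (0.88 + 0.6\,X_{wb}/100)\times10^{-7}$ (Riedel) and
$k = 0.148 + 0.493\,X_{wb}/100$ (Sweat), plus $\rho = m/(\pi R^2 L)$.
They are accepted on $[0, 100]$ % wet basis with a warning outside
[60, 98] %, the range typical of fresh produce. Biot numbers are computed
from the *unrounded* conductivity chain $k = \alpha\rho C_p$; rounding
happens only at presentation. The three correlations are mutually
consistent to about 10 % over 80–95 % moisture, which the tests document
but deliberately do not assert tighter.

## The synthetic-data generator

`synth_design()`/`generate_observations()` produce centre-point cooling
curves from a known truth: the exact forward curve plus i.i.d. Gaussian
noise, seeded explicitly, written on the °C scale of the three-column
experiment file dialect. Noise is additive on the dimensionless scale by
default (matching the fitting scale; sd maps to °C via
$|T_0 - T_{eq}|$), with a °C option. `carrot_design()` fixes the
reference study conditions: $R = 0.022$ m, $L = 0.040$ m,
$T_0 = 19.9$ °C, $T_{eq} = 3.5$ °C, truth $\alpha = 1.43\times10^{-7}$
m²/s and $h' = 6.92/(1003\times3918)$ m/s ($Bi_1 = 0.271$,
$Bi_2 = 0.246$), and 49 equally spaced samples over one hour. The hour
span and uniform spacing are a choice — the reference experiment's
sampling grid is not recorded beyond its 49 points — made so the curve
approaches equilibrium ($T^* \approx 0.04$ at 3600 s) the way a chilling
run is normally terminated.

What the generator does *not* emulate: sensor lag and probe conduction,
coolant temperature fluctuation, evaporative moisture loss, and
autocorrelated noise. Passing tests on synthetic data therefore
demonstrate the estimator's correctness and calibration under the model's
own assumptions, not robustness to these real-data effects.

## Kinetics summaries and regimes

`max_center_surface_gap()` scans $T^*(0,0,t) - T^*(R,0,t)$ on a uniform
grid (default 1 s over 0–3600 s). At the reference parameters the gap
peaks near 0.11 around 690 s; the maximum is very flat — the scanned gap
changes by under $10^{-3}$ when the step is refined from 10 s to 1 s,
and stays within 0.2 % of its peak over roughly a minute on either side —
so the *abscissa* of the maximum is ill-conditioned even though the gap
value itself is robust. The scan step `dt` is exposed for this reason.

`classify_regime()` applies the conventional thresholds: both Biot
numbers below 0.1 → lumped capacitance (only $h$ identifiable); both
above 40 → effectively first-kind boundary (only $\alpha$ identifiable);
otherwise the third-kind model, where both parameters can be estimated
simultaneously — the regime the reference chilling experiment occupies.

## Numerical choices, in one place

* Bisection everywhere (Bessel zeros, eigenvalues), bracket tolerance
  $10^{-12}$, analytic brackets; no derivative-based root polishing.
* 200 series terms per sub-problem by default; expansions are memoised
  per (kind, Biot, terms) since the optimizer revisits nearby Biot values.
* $Bi \ge 10^8$ treated as infinite; $Bi = 0$ rejected.
* Finite-difference step $10^{-3}$ relative, with an absolute floor for
  a zero parameter.
* LM: $\lambda_0 = 10^{-3}$, ×10/÷10 schedule, positivity by step
  halving, max 100 iterations, convergence at $10^{-5}$ relative.
* Covariance unscaled ($M^{-1}$); optional reduced-$\chi^2$ rescaling.
* Temperatures in °C throughout; only differences enter the model.
* Degenerate inputs fail loudly: $T_0 = T_{eq}$, non-positive sigma,
  points outside the cylinder, negative time, fewer than 3 observations.

## Known limitations

Constant properties and constant $T_{eq}$ (no freezing, no variable-rate
pasteurisation regimes); a single $h_H$ on all faces; two fitted
parameters only (lumped and first-kind models are forward-evaluated, not
fitted); no Bayesian posterior — the covariance-based intervals rely on
local quadratic behaviour of $\chi^2$, which the Monte-Carlo calibration
supports at the reference design's noise level but which may degrade for
very short or very noisy records.
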