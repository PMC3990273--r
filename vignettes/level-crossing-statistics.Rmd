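---
title: "Coordinated threshold crossings of correlated Gaussian processes: models, series, and their validation"
author: "levelxing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated threshold crossings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levelxing)
```

## The model

`levelxing` works with a pair of zero-mean stationary Gaussian processes
$V_1(t), V_2(t)$ — in the motivating neuroscience application, the membrane
potentials of two neurons driven by overlapping pools of synaptic inputs —
with

* autocovariances $\langle V_j(0)V_j(\tau)\rangle = \sigma_{V_j}^2 c(\tau)$,
* cross-covariance $\langle V_1(0)V_2(\tau)\rangle = r\,\sigma_{V_1}\sigma_{V_2}\,c(\tau)$,

where $c$ is a shared correlation kernel with $c(0)=1$ and $r\in[0,1)$ the
input correlation strength ($r=0$: independent; the singular limit $r=1$:
identical normalized processes, admitted only in the simulator). A "spike"
is an upward crossing of a common threshold $\psi$. Both processes must be
twice mean-square differentiable, i.e. $c''(0)$ finite; the correlation
time is defined through the curvature at the origin,
$\tau_s = \sqrt{c(0)/|c''(0)|}$, so that the derivative SD is
$\sigma_{V'} = \sigma_V/\tau_s$ for every built-in kernel.

Three kernel families are provided (`make_kernel()`), all with exact
analytic derivatives:

| family | $c(\tau)$ | notes |
|---|---|---|
| `sech` | $1/\cosh(\tau/\tau_s)$ | default; heavy-ish exponential tails |
| `gaussian` | $e^{-\tau^2/2\tau_s^2}$ | fastest-decaying choice |
| `double_lowpass` | $\frac{\tau_M e^{-|\tau|/\tau_M}-\tau_I e^{-|\tau|/\tau_I}}{\tau_M-\tau_I}$ | two cascaded low-pass filters (membrane and synaptic); parameterized by $\tau_s=\sqrt{\tau_M\tau_I}$ and the ratio $\tau_I/\tau_M$, with the analytic limit $(1{+}|\tau|/\tau_s)e^{-|\tau|/\tau_s}$ at ratio 1 |

`kernel_validate()` reports (without gating) the conditions the theory
needs: normalization, flat top, negative curvature, boundedness, symmetry,
truncated integrability of $|c|,|c'|,|c''|$, and integrability of
$(c''(s)-c''(0))/s$ near zero, which guarantees finite second moments of
crossing counts.

Units are fixed as mV and ms throughout; rates are converted to Hz only at
the reporting boundary (`rice_rate(..., units = "Hz")`).

## Rates and the conditional crossing rate

The Rice rate of each process is
$\nu_j = \frac{\sigma_{V_j'}}{2\pi\sigma_{V_j}}e^{-\psi^2/2\sigma_{V_j}^2}$.
The central object is the conditional rate
$\nu_{\mathrm{cond}}(\tau) = \langle s_1(t)s_2(t+\tau)\rangle/(\nu_1\nu_2)$,
the factor by which coincident crossings at lag $\tau$ exceed chance. The
joint intensity factorizes into the bivariate voltage density at the
threshold times a truncated second moment of the derivatives conditioned on
both voltages sitting at $\psi$:

$$\langle s_1 s_2\rangle(\tau) =
  \mathbb{E}\!\left[V_1'(0)^+\,V_2'(\tau)^+ \,\middle|\, V_1(0)=V_2(\tau)=\psi\right]
  \, p_\tau(\psi,\psi).$$

The conditional moment is evaluated by regressing the derivatives on the
voltages, $V_1' = \alpha_1 V_1 + \alpha_2 V_2 + \varepsilon_1$,
$V_2' = \beta_1 V_1 + \beta_2 V_2 + \varepsilon_2$
(`regression_coefficients()`, which also verifies itself against the 2×2
normal equations in the tests), and expanding the residual dependence with
Mehler's formula into a Hermite series (`cab_series()`). The series
converges geometrically in the residual correlation ratio
$|\mathrm{Cov}(\varepsilon_1,\varepsilon_2)|/(\sigma_{\varepsilon_1}\sigma_{\varepsilon_2}) < 1$
for $r<1$.

Numerical choices:

* **Truncation.** Default `n_max = 10`; in practice order $n=1$ is already
  within a few percent of the converged value for moderate $r$. Adaptive
  early stop when *two consecutive* terms fall below
  $10^{-12}\times$ the partial sum (thresholds at zero lag zero out every
  other term exactly, so a single-term criterion would stop prematurely). A
  warning is emitted when the convergence ratio exceeds 0.95 (the
  $r\to1,\tau\to0$ corner); the quadrature oracle is authoritative there.
* **Hermite polynomials** use the probabilists' convention via the stable
  three-term recurrence.
* **Negative lags** are evaluated directly through the signed kernel
  derivatives (the cross block is odd in $\tau$), never by mirroring; for
  $\sigma_{V_1}\neq\sigma_{V_2}$ the curve is genuinely asymmetric — the
  lower-rate process crosses on average after the higher-rate one.
* **Negative $r$** is admitted analytically by `process_pair()` (all closed
  forms extend to anticorrelated pairs); it is needed internally by the
  centered finite-difference oracle for the Taylor expansion. The
  shared-noise construction that motivates the model only realizes
  $r\in[0,1)$.

### The quadrature oracle

`nu_cond_oracle()` computes the same quantity by direct numerical
integration, independent of the Hermite series. The positive-quadrant
moment $\mathbb{E}[Y_1^+Y_2^+]$ of the conditional bivariate normal is
reduced to a *one-dimensional* adaptive integral through
$\mathbb{E}[W^+] = m\Phi(m/s) + s\phi(m/s)$ applied to the conditional law
of $Y_2$ given $Y_1$. This reduction is numerically robust arbitrarily
close to the degenerate $|\rho|\to1$ limit, where naive 2-D adaptive
quadrature fails; the inner integral uses a relative tolerance of
$10^{-10}$ on a $[0,\mu_1+12\sigma_1]$ range. The test suite holds series
and oracle to a relative gap below $10^{-3}$ across
$r\in\{0.1,\dots,0.8\}$, $\tau/\tau_s\in\{0,0.5,1,2,5\}$, for equal and
unequal variances.

### Zero lag

At $\tau=0$ a variable substitution makes the four-dimensional Gaussian
integral tractable and yields the exact value implemented in
`nu_cond_zero_lag()`:

$$\nu_{\mathrm{cond}}(0)=
\frac{1+\tfrac{2r}{\sqrt{1-r^2}}\arctan\sqrt{\tfrac{1+r}{1-r}}}
     {4\pi^2\nu_1\nu_2\tau_s^2}
\exp\!\left(-\frac{\psi^2}{4\sigma_{V_1}^2\sigma_{V_2}^2}
\left[\frac{(\sigma_{V_1}{+}\sigma_{V_2})^2}{1+r}
     +\frac{(\sigma_{V_2}{-}\sigma_{V_1})^2}{1-r}\right]\right).$$

Because $\sigma_{V'}=\sigma_V/\tau_s$ holds exactly for the built-in
kernels, the prefactor identity
$4\pi^2\nu_1\nu_2\tau_s^2=e^{-\psi^2/2\sigma_{V_1}^2-\psi^2/2\sigma_{V_2}^2}$
is used to regroup the exponent so that $r=0$ returns *exactly* 1 in
floating point. The value is cross-checked in three independent ways:
against the quadrature oracle at $\tau=0$ (relative gap $<10^{-4}$),
against the series evaluated at $\tau=10^{-3}\tau_s$, and against the
series evaluated directly at $\tau=0$, where it converges with ratio $r$.

### Taylor expansion in the correlation strength

For an identical pair, `nu_cond_taylor()` expands the normalized joint
intensity $\langle s_1 s_2\rangle/\nu$ as
$\nu(1 + rT_1 + r^2T_2 + r^3T_3)$, $u=\psi/\sigma_V$:

* $T_1 = c\,u^2 - \pi\tau_s^2 c''/2$,
* $T_2 = \tfrac12\!\left[c^2(u^2-1)^2 + \tau_s^2c''(c''\tau_s^2-\pi c u^2)
  + \tau_s^2c'^2\!\left(u^2(2-\pi)-2\right)\right]$,
* $T_3 = \tfrac{c^3}{6}(u^3-3u)^2 - \tfrac{\pi}{4}c^2c''\tau_s^2(u^2-1)^2
  + \tfrac12 c\,c''^2\tau_s^4u^2 + c'^2c''\tau_s^4u^2
  + c\,c'^2\tau_s^2\!\left[(1-\tfrac{\pi}{2})u^4+(\pi-3)u^2-\tfrac{\pi}{2}\right]$.

The first two orders reproduce the known weak-correlation limits. The
third-order coefficient was derived symbolically from the Hermite series
itself (the structured terms $c^q H_q(u)^2/q!$ are clearly visible) and is
pinned down in the tests by a finite-difference oracle: derivatives of the
full series at $r=0$ are extracted from a degree-8 polynomial fit on a
9-point symmetric stencil ($h=0.04$), accurate to $\sim10^{-6}$ relative
for the third derivative, and must match the implemented brackets to
$10^{-4}$.

## The bivariate count CLT

Counts of crossings in bins $[0,T]$, centered and divided by $\sqrt{T}$,
converge for $T\to\infty$ to a centered bivariate normal with covariance
matrix $\begin{pmatrix}a_{11}&a_{12}\\a_{12}&a_{22}\end{pmatrix}$. The
package computes the three series by a Wiener-chaos (Hermite order)
decomposition of the count functional
$U = \int \delta_\psi(X)\,X'^+\,\mathrm{d}s$ for the *rescaled* processes
(unit variance, unit derivative variance, time in units of $\tau_s$,
thresholds $\psi_i=\psi/\sigma_{V_i}$):

* the delta-function coefficients $d_j(\psi)=\phi(\psi)H_j(\psi)/j!$ and
  positive-part coefficients
  $a_k=\frac{1}{k!}\int_0^\infty xH_k(x)\phi(x)\,\mathrm{d}x$
  (closed form: $a_0=\phi(0)$, $a_1=\tfrac12$,
  $a_k=[H_k(0)+kH_{k-2}(0)]\phi(0)/k!$, zero for odd $k\ge3$) are
  tabulated by `hermite_basis()`;
* the order-$q$ contribution integrates a finite Mehler sum of kernel
  powers $c^{d_1}c'^{d_2}(-c')^{d_3}(-c'')^{d_4}$ over the lag
  (`mehler_cross_moment()`, `chaos_order_covariance()`);
* cross-contributions carry the factor $r^q$ — applied once, on the same
  code path as the variance, so the identity
  $\sigma_{X_1X_2}(q)=r^q\sigma^2_{X_1}(q)$ for identical marginals is
  exact by construction. Hence $a_{12}=0$ exactly at $r=0$, and the
  asymptotic Pearson coefficient $\rho=a_{12}/\sqrt{a_{11}a_{22}}$
  (`asymptotic_pearson()`) is an $r^q$-weighted average: sublinear in $r$,
  $\rho(r)\le r$, approaching 1 monotonically as $r\to1$.

Quadrature: the semi-infinite lag integrals are truncated where
$\max(|c|,|c'|,|c''|)<10^{-12}$ (about $30\tau_s$ for sech) and evaluated
by composite Simpson on 4001 nodes; order-1 values agree with an
independent closed-form evaluation to $10^{-8}$ relative.

### Convergence of the variance series, and an independent oracle

The derivative part of the count functional, $x^+$, has polynomially
decaying Hermite coefficients, so the *variance* series converges only
polynomially in the order $q$ — and slowly for small rescaled thresholds.
At $\psi=0.3$ (sech, $\tau_s=1$) the partial sums of $a_{11}$ are 0.040 at
$Q=10$ and still 0.051 at $Q=50$. The package therefore ships an
independent classical oracle, `count_variance_rice()`: the long-run
variance of one process's counts from the second-moment formula
$\nu + 2\int_0^T(1-s/T)\,(p_2(s)-\nu^2)\,\mathrm{d}s$, with $p_2(s)$ the
same-process joint crossing intensity evaluated by quadrature. At
$\psi=0.3$ it gives $a_{11}\approx0.061$ asymptotically
($\approx0.063$ at $T=50\tau_s$), which the simulator reproduces within
Monte Carlo error. *Consequence:* truncated chaos sums at moderate $Q$
understate the count variance at small thresholds (by $\approx35\%$ at
$Q=10$, $\psi=0.3$); the per-order decomposition is exact, but quantitative
variance predictions at small $\psi$ should use the classical oracle or
large $Q$ with the reported tail estimate. Cross-covariances at $r<1$ are
unaffected in practice because $r^q$ suppresses the tail geometrically.

A literal transcription of a commonly quoted closed form for the first two
orders is kept in `closed_form_sigma12()` purely as a cross-check surface.
Order 1 agrees with the general machinery to $10^{-8}$; the quoted order-2
expression evaluates to exactly **twice** the machinery value for every
kernel and threshold tested. The general machinery is authoritative — it
is validated against the classical variance oracle and against direct
simulation — and the tests record the factor-2 disagreement rather than
asserting it away.

## The simulator

`simulate_pair()` / `simulate_spike_trains()` synthesize the pair as
$V_1=\sigma_{V_1}(\sqrt{1-r}\,Z_1+\sqrt{r}\,Z_c)$,
$V_2=\sigma_{V_2}(\sqrt{1-r}\,Z_2+\sqrt{r}\,Z_c)$ from three independent
unit-variance stationary paths sharing the kernel. Design choices:

* **Circulant embedding** of the covariance sequence $c(k\,\Delta t)$ gives
  *exact* stationary Gaussian sampling (no spectral-quadrature error); the
  FFT grid is the next power of two above $2(n-1)$. Round-off-scale
  negative eigenvalues are clipped silently; deficits beyond
  $10^{-8}\times$ the largest eigenvalue trigger a warning.
* **Sub-streams.** The three generating paths consume three RNG sub-streams
  derived from the master seed, so sweeping $r$ holds the underlying noise
  fixed (variance reduction for correlation sweeps). Generation is
  bit-reproducible given (seed, config).
* **Discretization.** Default $\Delta t=\tau_s/50$; crossing detection uses
  the strict below / at-or-above convention $V_i<\psi\le V_{i+1}$ with
  linear interpolation of the crossing time, which counts tangential
  touches once and misses between-sample excursions at rate
  $O(\Delta t^2)$ for twice-differentiable kernels. The tests include a
  $\Delta t$-halving consistency check.
* **Counting.** Bins are half-open $[kT,(k+1)T)$; edge bins shorter than
  $T$ are discarded, not padded. Normalized deviations divide centered
  counts by $\sqrt{T/\tau_s}$, matching the rescaled-time units in which
  the $a_{ij}$ are stated.
* **Estimators.** `empirical_nucond()` is the pairwise cross-correlogram
  normalized by $\nu_1\nu_2\,\Delta_{\mathrm{bin}}\,(T_{\mathrm{dur}}-|\tau|)$
  with per-lag standard errors across realizations;
  `empirical_count_covariance()` is the unbiased sample covariance with
  large-sample standard errors attached.

### What the generator emulates — and what it does not

The simulator reproduces exactly the stationary bivariate Gaussian law of
the analytic model: matching auto-/cross-covariances, exact marginals, and
the shared/private noise decomposition. It deliberately does **not**
include reset dynamics after a crossing (integrate-and-fire behaviour),
non-Gaussian or nonstationary inputs, more than two channels, or unequal
thresholds. Passing tests therefore demonstrate the internal consistency
of formulas, oracles and sampler under the model's own assumptions; they
do not certify the Gaussian level-crossing description of any particular
real system, where resets, adaptation and input non-Gaussianity can all
move crossing statistics away from these predictions.

## The joint-Gaussianity battery

`projection_normality()` applies the Shapiro–Wilk test to the projections
$X_i^\top(\cos\theta,\sin\theta)$ on a deterministic uniform grid of 64
directions (a random vector is jointly Gaussian iff every linear projection
is univariate Gaussian); `mahalanobis_chi2()` compares the plug-in squared
Mahalanobis distances with the $\chi^2_2$ law (mean 2, KS statistic, QQ
pairs). Multiple testing across directions is *reported* (minimum p,
Bonferroni-adjusted verdict at 1%) but not silently enforced. Shapiro–Wilk
is validated up to $n=5000$; larger samples are reduced by a fixed-seed
subsample, the same indices for every direction.

**A caveat that matters in practice:** crossing counts are integers. For
short bins the counts per bin are small (mean $\approx3.8$ at
$T=25\tau_s$, $\psi=0.3$) and live on a lattice of $\sim$10 values; at
$n=5000$ the Shapiro–Wilk test has overwhelming power against this
discreteness and rejects in *every* direction, even though a continuous
bivariate normal with the same covariance passes and a *discretized*
Gaussian surrogate fails identically. In that regime the battery measures
the granularity of the counts, not a failure of joint Gaussianity; the
Mahalanobis mean and QQ diagnostics remain informative. Projection
p-values should be read against a discretized-surrogate baseline whenever
bins hold fewer than a few tens of crossings.

## Problem sizes and tolerances used in the test suite

The suite validates at the following scales, chosen to make the stochastic
bands (3–4 standard errors) decisive while keeping the default run
desk-sized: series/oracle agreement on a $5\times5\times2$ parameter grid
(relative $10^{-3}$ at `n_max = 30`); conditional-rate recovery from
$N=2000$ realizations of 20 s; count-variance recovery at $T=50\tau_s$
from $N=5000$ (acceptance) and $N=1500$ (unit) realizations; the
Gaussianity battery on $N=10^4$ count realizations and calibration across
60 seeds of exact bivariate normals. Known-red checks are kept red rather
than loosened: the $Q=10$ truncated $a_{11}$ against Monte Carlo at
$\psi=0.3$ (slow polynomial convergence, see above), its $r=1$
cross-covariance analogue, and the projection battery's minimum-p
criterion on small-mean integer counts (lattice discreteness, see above).

## Limitations

* The conditional-rate series is for a *common* threshold; rate
  heterogeneity is expressed through unequal variances.
* Exactly two processes; the chaos machinery generalizes in principle but
  is not implemented for more channels.
* Near $r\to1$ with $\tau\to0$ the series converges slowly (ratio
  $\to1$); use `nu_cond_oracle()` there.
* Truncated chaos sums understate variances at small rescaled thresholds;
  see the convergence discussion above.
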