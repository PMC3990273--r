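#' Rice rate of threshold upcrossings
#'
#' Expected number of upward crossings of the level `psi` per unit time for a
#' stationary Gaussian process with standard deviation `sigma_v` and
#' correlation kernel `kernel`:
#' `nu = sigma_vp / (2 pi sigma_v) * exp(-psi^2 / (2 sigma_v^2))` with
#' `sigma_vp = sigma_v * sqrt(|c''(0)|)`. The rate is maximal at `psi = 0`
#' and decreases monotonically in `|psi|`; it depends on `psi` and `sigma_v`
#' only through their ratio.
#'
#' @param sigma_v Voltage standard deviation (mV), positive.
#' @param kernel A [make_kernel()] object.
#' @param psi Threshold (mV); vectorized.
#' @param units `"Hz"` (default) or `"per_ms"`. Internally all rates are per
#'   ms; the ms-to-s conversion happens only at this reporting boundary.
#' @return Upcrossing rate(s), strictly positive.
#' @examples
#' k <- make_kernel("sech", tau_s = 20)
#' rice_rate(10, k, 9.64)  # 5.00 Hz
#' rice_rate(5, k, 9.64)   # 1.24 Hz
#' @export
rice_rate <- function(sigma_v, kernel, psi, units = c("Hz", "per_ms")) {
  units <- match.arg(units)
  stopifnot(inherits(kernel, "corr_kernel"))
  if (!is.numeric(sigma_v) || any(sigma_v <= 0)) {
    stop("'sigma_v' must be positive")
  }
  sp <- sigma_v * sqrt(-kernel$c2_0)
  nu <- sp / (2 * pi * sigma_v) * exp(-psi^2 / (2 * sigma_v^2))
  if (units == "Hz") nu * 1000 else nu
}

# regression of the two derivatives on the two voltages, from raw covariance
# entries; shared by the pair interface and the single-process (r = 1
# structure) variance oracle
regress_from_sigma <- function(s1sq, s2sq, sp1sq, sp2sq, S13, S14, S24, psi) {
  D <- s1sq * s2sq - S13^2
  if (D <= 0) stop("degenerate conditioning block: sigma1^2 sigma2^2 - Sigma13^2 <= 0")
  alpha1 <- S14 * S13 / D
  alpha2 <- -S14 * s1sq / D
  beta1 <- s2sq * S14 / D
  beta2 <- -S14 * S13 / D
  v1 <- sp1sq - (alpha1^2 * s1sq + 2 * alpha1 * alpha2 * S13 + alpha2^2 * s2sq)
  v2 <- sp2sq - (beta1^2 * s1sq + 2 * beta1 * beta2 * S13 + beta2^2 * s2sq)
  sigma_eps1 <- sqrt(max(v1, 0))
  sigma_eps2 <- sqrt(max(v2, 0))
  cov_eps <- S24 - (beta1 * alpha1 * s1sq + (alpha1 * beta2 + alpha2 * beta1) * S13 +
                      alpha2 * beta2 * s2sq)
  list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
       sigma_eps1 = sigma_eps1, sigma_eps2 = sigma_eps2, cov_eps = cov_eps,
       mu1 = psi * (alpha1 + alpha2), mu2 = psi * (beta1 + beta2),
       a = -psi * (alpha1 + alpha2) / sigma_eps1,
       b = -psi * (beta1 + beta2) / sigma_eps2)
}

#' Regression of the voltage derivatives on the voltages
#'
#' Conditioning `(V1'(0), V2'(tau))` on `(V1(0), V2(tau)) = (psi, psi)` is
#' done through the linear regression `V1' = alpha1 V1 + alpha2 V2 + eps1`,
#' `V2' = beta1 V1 + beta2 V2 + eps2` with residuals independent of the
#' voltages. The returned coefficients, residual standard deviations
#' `sigma_eps1`, `sigma_eps2`, residual covariance `cov_eps` and the
#' standardized truncation bounds `a`, `b` parameterize the Hermite series of
#' the joint crossing intensity, see [cab_series()].
#'
#' At `tau = 0` (any even kernel) all four weights vanish because
#' `Sigma14(0) = 0`, hence `a = b = 0` and the residual SDs reduce to the
#' derivative SDs.
#'
#' @param pair A [process_pair()].
#' @param tau Lag (ms), scalar.
#' @return Object of class `regression_coefficients`.
#' @export
regression_coefficients <- function(pair, tau) {
  stopifnot(inherits(pair, "process_pair"))
  cc <- covariance_matrix(pair, tau)
  rc <- regress_from_sigma(pair$sigma_v1^2, pair$sigma_v2^2,
                           pair$sigma_vp1^2, pair$sigma_vp2^2,
                           cc$Sigma13, cc$Sigma14, cc$Sigma24, pair$psi)
  structure(c(list(tau = tau), rc), class = "regression_coefficients")
}

#' @export
print.regression_coefficients <- function(x, ...) {
  cat(sprintf("<regression_coefficients> tau = %g ms\n", x$tau))
  cat(sprintf("  alpha = (%.4g, %.4g), beta = (%.4g, %.4g) per ms\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  cat(sprintf("  sigma_eps = (%.4g, %.4g) mV/ms, cov_eps = %.4g, a = %.4g, b = %.4g\n",
              x$sigma_eps1, x$sigma_eps2, x$cov_eps, x$a, x$b))
  invisible(x)
}

# Hermite series for the truncated second moment
#   C(a,b) = E[ Y1 1{Y1>=0} Y2 1{Y2>=0} | V1 = V2 = psi ]
# from regression coefficients; orders n = 0, 1 are the collapsed closed
# forms, orders n >= 2 use probabilists' Hermite polynomials
cab_from_regression <- function(rc, n_max = 10L, tol = 1e-12,
                                ratio_guard = 0.95) {
  se1 <- rc$sigma_eps1; se2 <- rc$sigma_eps2
  a <- rc$a; b <- rc$b
  ratio <- abs(rc$cov_eps) / (se1 * se2)
  if (ratio >= 1) stop("residual correlation ratio >= 1: series does not converge")
  if (ratio > ratio_guard) {
    warning(sprintf(
      "residual correlation ratio %.4f exceeds %.2f: series convergence is slow",
      ratio, ratio_guard))
  }
  phib <- function(x) stats::pnorm(x, lower.tail = FALSE)
  terms <- numeric(n_max + 1L)
  terms[1L] <- (b * phib(b) - stats::dnorm(b)) *
    (a * phib(a) - stats::dnorm(a)) * se1 * se2
  if (n_max >= 1L) terms[2L] <- phib(a) * phib(b) * rc$cov_eps
  value <- sum(terms[1:min(2L, n_max + 1L)])
  n_used <- min(n_max, 1L)
  converged <- FALSE
  if (n_max >= 2L) {
    pref <- stats::dnorm(a) * stats::dnorm(b)
    ha_m2 <- 1; ha_m1 <- a   # He_{n-2}(a) via recurrence
    hb_m2 <- 1; hb_m1 <- b
    lfac <- lgamma(seq_len(n_max + 1L))  # log((n)!) at index n
    for (n in 2:n_max) {
      hn2a <- if (n == 2L) 1 else if (n == 3L) a else {
        h <- a * ha_m1 - (n - 3L) * ha_m2; ha_m2 <- ha_m1; ha_m1 <- h; h
      }
      hn2b <- if (n == 2L) 1 else if (n == 3L) b else {
        h <- b * hb_m1 - (n - 3L) * hb_m2; hb_m2 <- hb_m1; hb_m1 <- h; h
      }
      terms[n + 1L] <- pref * hn2a * hn2b * rc$cov_eps^n /
        (exp(lfac[n + 1L]) * (se1 * se2)^(n - 1L))
      value <- value + terms[n + 1L]
      n_used <- n
      # thresholds at zero lag zero out every other term exactly, so require
      # two consecutive negligible terms before stopping early
      if (max(abs(terms[n + 1L]), abs(terms[n])) <
            tol * max(abs(value), .Machine$double.xmin)) {
        converged <- TRUE
        break
      }
    }
    terms <- terms[1:(n_used + 1L)]
  }
  structure(list(value = value, n_used = n_used, terms = terms,
                 ratio = ratio, converged = converged),
            class = "series_evaluation")
}

#' Hermite series for the conditional truncated moment C(a,b)(tau)
#'
#' Evaluates the uniformly convergent series for
#' `C(a,b)(tau) = E[V1'(0)^+ V2'(tau)^+ | V1(0) = V2(tau) = psi]`
#' obtained from the regression model and Mehler's formula. Order `n = 0` is
#' `[b Phibar(b) - phi(b)][a Phibar(a) - phi(a)] sigma_eps1 sigma_eps2`,
#' order `n = 1` is `Phibar(a) Phibar(b) cov_eps`, and orders `n >= 2` are
#' `phi(a) phi(b) He_{n-2}(a) He_{n-2}(b) cov_eps^n / (n! (sigma_eps1
#' sigma_eps2)^{n-1})` with probabilists' Hermite polynomials evaluated by
#' the three-term recurrence. The convergence ratio is
#' `|cov_eps| / (sigma_eps1 sigma_eps2) < 1` for `|r| < 1`; a warning is
#' emitted when it exceeds 0.95 (slow convergence near `r -> 1`, `tau -> 0`).
#'
#' @param pair A [process_pair()].
#' @param tau Lag (ms), scalar.
#' @param n_max Maximum truncation order (default 10).
#' @param tol Early-stop tolerance relative to the partial sum.
#' @return Object of class `series_evaluation` with fields `value`
#'   (mV^2/ms^2), `n_used`, `terms` (orders 0..n_used), `ratio`, `converged`.
#' @export
cab_series <- function(pair, tau, n_max = 10L, tol = 1e-12) {
  rc <- regression_coefficients(pair, tau)
  cab_from_regression(rc, n_max = n_max, tol = tol)
}

#' @export
print.series_evaluation <- function(x, ...) {
  cat(sprintf("<series_evaluation> value = %.6g, n_used = %d, ratio = %.4f, converged: %s\n",
              x$value, x$n_used, x$ratio, x$converged))
  invisible(x)
}

#' Joint intensity of coincident upcrossings
#'
#' The spike cross-correlation `<s1(t) s2(t+tau)>`: the joint intensity (per
#' ms^2) of an upcrossing of `psi` by `V1` at time `t` and by `V2` at
#' `t + tau`. Computed as the product of the conditional truncated moment
#' series [cab_series()] and the bivariate voltage density
#' [bivariate_density_at_threshold()]. At `r = 0`, and in the long-lag limit,
#' it factorizes into the product of the two Rice rates.
#'
#' @inheritParams cab_series
#' @return Intensity in 1/ms^2 (scalar).
#' @export
spike_cross_correlation <- function(pair, tau, n_max = 10L) {
  cab_series(pair, tau, n_max = n_max)$value *
    bivariate_density_at_threshold(pair, tau)
}

#' Conditional rate of coincident upcrossings
#'
#' `nu_cond(tau) = <s1(t) s2(t+tau)> / (nu1 nu2)`: the factor by which the
#' joint crossing intensity at lag `tau` exceeds the product of the two Rice
#' rates. Equals 1 for independent processes (`r = 0`) and tends to 1 as
#' `tau -> +-Inf`; it is an even function of `tau` exactly when
#' `sigma_v1 = sigma_v2`, and asymmetric otherwise (the lower-rate process
#' crosses on average after the higher-rate one).
#'
#' @param pair A [process_pair()].
#' @param tau Lag(s) in ms; vectorized. Negative lags are evaluated directly
#'   through the signed kernel derivatives, not by mirroring.
#' @param n_max Series truncation order (default 10).
#' @return Dimensionless conditional rate ratio, same length as `tau`.
#' @export
nu_cond <- function(pair, tau, n_max = 10L) {
  stopifnot(inherits(pair, "process_pair"))
  nu12 <- rice_rate(pair$sigma_v1, pair$kernel, pair$psi, units = "per_ms") *
    rice_rate(pair$sigma_v2, pair$kernel, pair$psi, units = "per_ms")
  vapply(tau, function(tt) {
    spike_cross_correlation(pair, tt, n_max = n_max) / nu12
  }, numeric(1L))
}

#' Exact zero-lag conditional rate
#'
#' Closed-form value of `nu_cond(0)`:
#' `[1 + 2 r arctan(sqrt((1+r)/(1-r))) / sqrt(1-r^2)] / (4 pi^2 nu1 nu2
#' tau_s^2) * exp(-(psi^2/(4 s1^2 s2^2)) [(s1+s2)^2/(1+r) +
#' (s2-s1)^2/(1-r)])`, with the rates in 1/ms. Because every built-in kernel
#' satisfies `sigma_vpj = sigma_vj / tau_s`, the prefactor identity
#' `4 pi^2 nu1 nu2 tau_s^2 = exp(-psi^2/(2 s1^2) - psi^2/(2 s2^2))` holds
#' exactly; the implementation groups the exponent so that `r = 0` returns
#' exactly 1 in floating point.
#'
#' @param pair A [process_pair()].
#' @return Dimensionless conditional rate ratio at `tau = 0`.
#' @export
nu_cond_zero_lag <- function(pair) {
  stopifnot(inherits(pair, "process_pair"))
  r <- pair$r
  s1 <- pair$sigma_v1; s2 <- pair$sigma_v2; psi <- pair$psi
  pre <- 1 + 2 * r * atan(sqrt((1 + r) / (1 - r))) / sqrt(1 - r^2)
  # exponent relative to the r = 0 value, which cancels the 1/(4 pi^2 nu1 nu2
  # tau_s^2) prefactor exactly
  expo <- -(psi^2 / (4 * s1^2 * s2^2)) *
    ((s1 + s2)^2 * (-r / (1 + r)) + (s2 - s1)^2 * (r / (1 - r)))
  pre * exp(expo)
}

#' Taylor expansion of the joint crossing intensity in the correlation
#'
#' For an identical pair (`sigma_v1 = sigma_v2 = sigma_v`) the normalized
#' joint intensity `<s1 s2>/nu` expands around `r = 0` as
#' `nu (1 + r T1 + r^2 T2 + r^3 T3 + O(r^4))` with, writing `u = psi/sigma_v`
#' and all kernel values at lag `tau`,
#' \deqn{T1 = c u^2 - \pi \tau_s^2 c''/2,}
#' \deqn{T2 = [c^2 (u^2-1)^2 + \tau_s^2 c'' (c'' \tau_s^2 - \pi c u^2)
#'   + \tau_s^2 c'^2 (u^2 (2-\pi) - 2)]/2,}
#' \deqn{T3 = c^3 (u^3 - 3u)^2/6 - (\pi/4) c^2 c'' \tau_s^2 (u^2-1)^2
#'   + c c''^2 \tau_s^4 u^2/2 + c'^2 c'' \tau_s^4 u^2
#'   + c c'^2 \tau_s^2 [(1-\pi/2) u^4 + (\pi-3) u^2 - \pi/2].}
#' The first two orders coincide with the known weak-correlation limits; the
#' cubic coefficient here is the exact third derivative of the full Hermite
#' series (obtained by symbolic expansion and confirmed by finite
#' differences). Dividing the result by `nu` gives the truncated `nu_cond`.
#'
#' @param pair A [process_pair()] with equal standard deviations. The pair's
#'   own `r` is used as the expansion variable.
#' @param tau Lag (ms); vectorized.
#' @param order Truncation order of the expansion, 1, 2 or 3.
#' @return `nu (1 + sum_k r^k Tk)` in 1/ms, same length as `tau`.
#' @export
nu_cond_taylor <- function(pair, tau, order = 3L) {
  stopifnot(inherits(pair, "process_pair"))
  if (abs(pair$sigma_v1 - pair$sigma_v2) > 1e-12 * pair$sigma_v1) {
    stop("the Taylor expansion is defined for an identical pair (sigma_v1 == sigma_v2)")
  }
  if (!order %in% 1:3) stop("'order' must be 1, 2 or 3")
  k <- pair$kernel
  ts <- sqrt(1 / abs(k$c2_0))
  u <- pair$psi / pair$sigma_v1
  c0 <- k$c0(tau); c1 <- k$c1(tau); c2 <- k$c2(tau)
  nu <- rice_rate(pair$sigma_v1, k, pair$psi, units = "per_ms")
  T1 <- c0 * u^2 - pi * ts^2 * c2 / 2
  acc <- 1 + pair$r * T1
  if (order >= 2L) {
    T2 <- (c0^2 * (u^2 - 1)^2 +
             ts^2 * c2 * (c2 * ts^2 - pi * c0 * u^2) +
             ts^2 * c1^2 * (u^2 * (2 - pi) - 2)) / 2
    acc <- acc + pair$r^2 * T2
  }
  if (order >= 3L) {
    T3 <- c0^3 * (u^3 - 3 * u)^2 / 6 -
      (pi / 4) * c0^2 * c2 * ts^2 * (u^2 - 1)^2 +
      c0 * c2^2 * ts^4 * u^2 / 2 +
      c1^2 * c2 * ts^4 * u^2 +
      c0 * c1^2 * ts^2 * ((1 - pi / 2) * u^4 + (pi - 3) * u^2 - pi / 2)
    acc <- acc + pair$r^3 * T3
  }
  nu * acc
}

# E[Y1+ Y2+] for a bivariate normal (mu1, mu2, s1, s2, cov), reduced to a 1D
# adaptive integral through E[W+] = m Phi(m/s) + s phi(m/s) for the
# conditional law of Y2 given Y1; robust up to the degenerate |rho| -> 1 limit
positive_quadrant_moment <- function(mu1, mu2, s1, s2, cov12,
                                     rel_tol = 1e-10) {
  rho <- cov12 / (s1 * s2)
  s_cond <- s2 * sqrt(max(1 - rho^2, 0))
  f <- function(y1) {
    m <- mu2 + (cov12 / s1^2) * (y1 - mu1)
    ew <- if (s_cond > 0) {
      m * stats::pnorm(m / s_cond) + s_cond * stats::dnorm(m / s_cond)
    } else {
      pmax(m, 0)
    }
    y1 * stats::dnorm(y1, mean = mu1, sd = s1) * ew
  }
  upper <- mu1 + 12 * s1
  if (upper <= 0) return(0)
  stats::integrate(f, 0, upper, rel.tol = rel_tol, abs.tol = 1e-14,
                   subdivisions = 500L)$value
}

# joint crossing intensity (1/ms^2) from raw covariance entries, by
# quadrature; shared by nu_cond_oracle and count_variance_rice
crossing_intensity_quadrature <- function(s1, s2, sp1, sp2, S13, S14, S24,
                                          psi, rel_tol = 1e-10) {
  rc <- regress_from_sigma(s1^2, s2^2, sp1^2, sp2^2, S13, S14, S24, psi)
  m2 <- positive_quadrant_moment(rc$mu1, rc$mu2, rc$sigma_eps1, rc$sigma_eps2,
                                 rc$cov_eps, rel_tol = rel_tol)
  det <- s1^2 * s2^2 - S13^2
  dens <- exp(-(psi^2 * (s1^2 + s2^2) - 2 * psi^2 * S13) / (2 * det)) /
    (2 * pi * sqrt(det))
  m2 * dens
}

#' Quadrature oracle for the conditional rate
#'
#' Direct numerical evaluation of
#' `nu_cond(tau) = Int Int v1 v2 p_tau(psi, v1, psi, v2) dv1 dv2 / (nu1 nu2)`
#' over the positive quadrant of the derivatives, independent of the Hermite
#' series: the conditional law of `(V1'(0), V2'(tau))` given both voltages at
#' threshold is bivariate normal, and the quadrant moment is reduced to a 1D
#' adaptive integral via the conditional-expectation identity
#' `E[W+] = m Phi(m/s) + s phi(m/s)`. Serves as ground truth for
#' [nu_cond()] in tests, including near `r -> 1` where the series converges
#' slowly.
#'
#' @param pair A [process_pair()].
#' @param tau Lag(s) in ms; vectorized.
#' @param rel_tol Relative tolerance of the inner adaptive integral.
#' @return Dimensionless conditional rate ratio.
#' @export
nu_cond_oracle <- function(pair, tau, rel_tol = 1e-10) {
  stopifnot(inherits(pair, "process_pair"))
  k <- pair$kernel
  s1 <- pair$sigma_v1; s2 <- pair$sigma_v2
  nu12 <- rice_rate(s1, k, pair$psi, units = "per_ms") *
    rice_rate(s2, k, pair$psi, units = "per_ms")
  vapply(tau, function(tt) {
    S13 <- pair$r * s1 * s2 * k$c0(tt)
    S14 <- pair$r * s1 * s2 * k$c1(tt)
    S24 <- -pair$r * s1 * s2 * k$c2(tt)
    crossing_intensity_quadrature(s1, s2, pair$sigma_vp1, pair$sigma_vp2,
                                  S13, S14, S24, pair$psi,
                                  rel_tol = rel_tol) / nu12
  }, numeric(1L))
}

#' Long-run variance of upcrossing counts of a single process (classical
#' oracle)
#'
#' The limit `Var(U_[0,T]) / T` for the upcrossing counts of one unit-variance
#' process with kernel `c` and threshold `psi`, from the classical
#' second-moment formula `nu + 2 Int_0^T (1 - s/T)(p2(s) - nu^2) ds`, where
#' `p2(s)` is the joint intensity of two crossings of the same process at lag
#' `s` (the `r = 1` covariance structure), evaluated by quadrature. With
#' `bin_T = Inf` this is the asymptotic count variance that the Hermite chaos
#' series [count_covariance_series()] converges to; at finite `bin_T` it is
#' the exact finite-bin value. Time is measured in the kernel's own units.
#'
#' @param psi Threshold for the unit-variance process (dimensionless).
#' @param kernel A [make_kernel()] object (use `tau_s = 1` for the rescaled
#'   process).
#' @param bin_T Bin length; `Inf` for the asymptotic limit.
#' @param s_max Truncation lag of the integral; defaults to the kernel
#'   support.
#' @param n_grid Number of quadrature nodes for the lag integral.
#' @return Long-run count variance per unit time (dimensionless).
#' @export
count_variance_rice <- function(psi, kernel, bin_T = Inf, s_max = NULL,
                                n_grid = 301L) {
  stopifnot(inherits(kernel, "corr_kernel"))
  if (is.null(s_max)) s_max <- min(kernel_support(kernel, eps = 1e-10),
                                   if (is.finite(bin_T)) bin_T else Inf)
  nu <- rice_rate(1, kernel, psi, units = "per_ms")
  ts <- kernel$tau_s
  p2 <- function(s) {
    S13 <- kernel$c0(s); S14 <- kernel$c1(s); S24 <- -kernel$c2(s)
    crossing_intensity_quadrature(1, 1, sqrt(-kernel$c2_0), sqrt(-kernel$c2_0),
                                  S13, S14, S24, psi, rel_tol = 1e-9)
  }
  # dense near zero where the intensity rises from 0, coarser in the tail
  sg <- unique(c(0, ts * 0.3 * (seq_len(30L) / 30L)^2,
                 seq(0.3 * ts, s_max, length.out = n_grid)))
  vals <- vapply(sg[-1L], p2, numeric(1L)) - nu^2
  vals <- c(-nu^2, vals)  # p2(0) = 0 for twice-differentiable kernels
  w <- if (is.finite(bin_T)) pmax(1 - sg / bin_T, 0) else rep(1, length(sg))
  integ <- sum(diff(sg) * (utils::head(vals * w, -1L) + utils::tail(vals * w, -1L)) / 2)
  nu + 2 * integ
}
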