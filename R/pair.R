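#' Bivariate Gaussian voltage model
#'
#' Defines a pair of zero-mean stationary Gaussian processes `V1`, `V2` with
#' standard deviations `sigma_v1`, `sigma_v2` (mV), a shared correlation
#' kernel `c(tau)`, a common spiking threshold `psi` (mV) and correlation
#' strength `r`: the autocovariances are `sigma_vj^2 c(tau)` and the
#' cross-covariance is `r sigma_v1 sigma_v2 c(tau)`. The derivative standard
#' deviations follow from the kernel curvature,
#' `sigma_vpj = sigma_vj * sqrt(|c''(0)|)` (mV/ms).
#'
#' `r = 1` (identical normalized processes) is excluded because it makes the
#' four-dimensional covariance of `(V1(0), V1'(0), V2(tau), V2'(tau))`
#' singular; the simulator accepts `r = 1` separately as a limiting
#' diagnostic. Negative `r` is admitted analytically (all closed forms extend
#' to anticorrelated pairs) although the shared-noise construction that
#' motivates the model only realizes `r` in `[0, 1)`.
#'
#' @param sigma_v1,sigma_v2 Voltage standard deviations in mV, positive.
#' @param psi Common threshold in mV.
#' @param r Correlation strength, in `(-1, 1)`.
#' @param kernel A [make_kernel()] object shared by both processes.
#' @return An object of class `process_pair`.
#' @examples
#' k <- make_kernel("sech", tau_s = 20)
#' p <- process_pair(10, 10, psi = 9.64, r = 0.7, kernel = k)
#' rice_rate(10, k, 9.64)  # about 5 Hz
#' @export
process_pair <- function(sigma_v1, sigma_v2, psi, r, kernel) {
  stopifnot(inherits(kernel, "corr_kernel"))
  if (!is.numeric(sigma_v1) || sigma_v1 <= 0 ||
      !is.numeric(sigma_v2) || sigma_v2 <= 0) {
    stop("'sigma_v1' and 'sigma_v2' must be positive (mV)")
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || abs(r) >= 1) {
    stop("'r' must lie strictly inside (-1, 1); r = 1 makes the joint ",
         "covariance singular")
  }
  if (!is.numeric(psi) || length(psi) != 1L || !is.finite(psi)) {
    stop("'psi' must be a finite number (mV)")
  }
  sp <- sqrt(-kernel$c2_0)
  structure(
    list(sigma_v1 = sigma_v1, sigma_v2 = sigma_v2,
         sigma_vp1 = sigma_v1 * sp, sigma_vp2 = sigma_v2 * sp,
         psi = psi, r = r, kernel = kernel),
    class = "process_pair"
  )
}

#' @export
print.process_pair <- function(x, ...) {
  cat(sprintf(
    "<process_pair> sigma = (%g, %g) mV, psi = %g mV, r = %g, %s kernel (tau_s = %g ms)\n",
    x$sigma_v1, x$sigma_v2, x$psi, x$r, x$kernel$family, x$kernel$tau_s))
  cat(sprintf("  Rice rates: %.4g Hz, %.4g Hz\n",
              rice_rate(x$sigma_v1, x$kernel, x$psi),
              rice_rate(x$sigma_v2, x$kernel, x$psi)))
  invisible(x)
}

#' Joint covariance of voltages and derivatives at lag tau
#'
#' Assembles the 4x4 covariance matrix of the Gaussian vector
#' `(V1(0), V1'(0), V2(tau), V2'(tau))`:
#' off-diagonal blocks `Sigma13 = r s1 s2 c(tau)` (mV^2),
#' `Sigma14 = r s1 s2 c'(tau)` (mV^2/ms) and
#' `Sigma24 = -r s1 s2 c''(tau)` (mV^2/ms^2), with the (2,3) entry equal to
#' `-Sigma14` by stationarity. The matrix is positive semidefinite for all
#' lags whenever `|r| < 1`.
#'
#' @param pair A [process_pair()].
#' @param tau Lag in ms (may be negative; `Sigma14` is odd in `tau`).
#' @return An object of class `cross_cov`: the matrix plus the named entries.
#' @export
covariance_matrix <- function(pair, tau) {
  stopifnot(inherits(pair, "process_pair"))
  k <- pair$kernel
  s1 <- pair$sigma_v1; s2 <- pair$sigma_v2
  S13 <- pair$r * s1 * s2 * k$c0(tau)
  S14 <- pair$r * s1 * s2 * k$c1(tau)
  S24 <- -pair$r * s1 * s2 * k$c2(tau)
  m <- matrix(c(
    s1^2,            0,               S13,  S14,
    0,               pair$sigma_vp1^2, -S14, S24,
    S13,             -S14,            s2^2, 0,
    S14,             S24,             0,    pair$sigma_vp2^2
  ), nrow = 4L, byrow = TRUE)
  dimnames(m) <- rep(list(c("V1", "V1p", "V2", "V2p")), 2L)
  structure(list(tau = tau, matrix = m,
                 Sigma13 = S13, Sigma14 = S14, Sigma24 = S24),
            class = "cross_cov")
}

#' @export
print.cross_cov <- function(x, ...) {
  cat(sprintf("<cross_cov> tau = %g ms\n", x$tau))
  print(x$matrix)
  invisible(x)
}

#' Bivariate Gaussian density of the two voltages at the threshold
#'
#' Value of the centered bivariate normal density of `(V1(0), V2(tau))`,
#' with variances `sigma_v1^2`, `sigma_v2^2` and covariance
#' `r sigma_v1 sigma_v2 c(tau)`, evaluated at the common threshold
#' `(psi, psi)`. This is the density factor multiplying the truncated-moment
#' series in the joint crossing intensity.
#'
#' @param pair A [process_pair()].
#' @param tau Lag in ms; vectorized.
#' @return Density values in 1/mV^2, strictly positive.
#' @export
bivariate_density_at_threshold <- function(pair, tau) {
  stopifnot(inherits(pair, "process_pair"))
  s1 <- pair$sigma_v1; s2 <- pair$sigma_v2
  S13 <- pair$r * s1 * s2 * pair$kernel$c0(tau)
  det <- s1^2 * s2^2 - S13^2
  if (any(det <= 0)) {
    stop("degenerate voltage covariance: |r c(tau)| must be < 1")
  }
  q <- (pair$psi^2 * s2^2 - 2 * pair$psi^2 * S13 + pair$psi^2 * s1^2) / det
  exp(-q / 2) / (2 * pi * sqrt(det))
}
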