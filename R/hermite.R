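#' Probabilists' Hermite polynomials
#'
#' `He_n(z) = (-1)^n e^{z^2/2} d^n/dz^n e^{-z^2/2}`, evaluated by the stable
#' three-term recurrence `He_{n+1}(z) = z He_n(z) - n He_{n-1}(z)` with
#' `He_0 = 1`, `He_1 = z`.
#'
#' @param n Non-negative integer order.
#' @param z Numeric vector of evaluation points.
#' @return Numeric vector of the same length as `z`.
#' @export
hermite_poly <- function(n, z) {
  if (length(n) != 1L || n < 0 || n != round(n)) {
    stop("'n' must be a single non-negative integer")
  }
  if (n == 0L) return(rep(1, length(z)))
  if (n == 1L) return(z)
  hm2 <- rep(1, length(z))
  hm1 <- z
  for (k in 2:n) {
    h <- z * hm1 - (k - 1) * hm2
    hm2 <- hm1
    hm1 <- h
  }
  hm1
}

#' Hermite coefficients of the positive-part function
#'
#' `a_k = (1/k!) Int_0^Inf x He_k(x) phi(x) dx`, the coefficients of the
#' expansion `x^+ = sum_k a_k He_k(x)` in the standard Gaussian weight.
#' Using `x He_k = He_{k+1} + k He_{k-1}` and
#' `Int_0^Inf He_m(x) phi(x) dx = He_{m-1}(0) phi(0)` (for `m >= 1`), the
#' closed form is `a_0 = phi(0)`, `a_1 = 1/2`, and for `k >= 2`
#' `a_k = [He_k(0) + k He_{k-2}(0)] phi(0) / k!`, which vanishes for odd
#' `k >= 3`.
#'
#' @param k Non-negative integer order; vectorized.
#' @return Numeric vector of coefficients.
#' @export
ak_coefficient <- function(k) {
  vapply(k, function(kk) {
    if (kk < 0 || kk != round(kk)) stop("'k' must be a non-negative integer")
    if (kk == 0L) return(stats::dnorm(0))
    if (kk == 1L) return(0.5)
    if (kk %% 2L == 1L) return(0)
    (hermite_poly(kk, 0) + kk * hermite_poly(kk - 2L, 0)) * stats::dnorm(0) /
      factorial(kk)
  }, numeric(1L))
}

#' Hermite basis tables for the count chaos expansion
#'
#' Precomputes, for a rescaled threshold `psi`, the delta-function
#' coefficients `d_j(psi) = phi(psi) He_j(psi) / j!` and the positive-part
#' coefficients `a_k` up to a maximum order. These are the building blocks of
#' the chaos expansion of the upcrossing count functional
#' `U = Int delta_psi(X) X'^+ ds`.
#'
#' @param psi Rescaled threshold (dimensionless, `psi / sigma_v` for a
#'   process with standard deviation `sigma_v`).
#' @param max_order Largest Hermite order tabulated.
#' @return Object of class `hermite_basis` with fields `psi`, `d` (orders
#'   `0..max_order`), `a` (same orders), `max_order`.
#' @export
hermite_basis <- function(psi, max_order = 12L) {
  stopifnot(is.numeric(psi), length(psi) == 1L, is.finite(psi),
            max_order >= 1L)
  j <- 0:max_order
  d <- vapply(j, function(jj) {
    stats::dnorm(psi) * hermite_poly(jj, psi) / factorial(jj)
  }, numeric(1L))
  structure(list(psi = psi, d = d, a = ak_coefficient(j),
                 max_order = as.integer(max_order)),
            class = "hermite_basis")
}

#' @export
print.hermite_basis <- function(x, ...) {
  cat(sprintf("<hermite_basis> psi = %g, orders 0..%d\n", x$psi, x$max_order))
  invisible(x)
}
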