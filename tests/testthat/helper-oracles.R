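# Independent oracles shared across test files. These deliberately avoid the
# package's own code paths: plain grid quadrature and textbook formulas only.

# E[f(X) g(Y)] for standard bivariate normal (X, Y) with correlation rho,
# by Simpson quadrature on a [-8, 8]^2 grid
bvn_expectation <- function(f, g, rho, n = 401L) {
  x <- seq(-8, 8, length.out = n)
  h <- x[2L] - x[1L]
  w <- c(1, rep(c(4, 2), (n - 3L) / 2L), 4, 1) * h / 3
  fx <- f(x); gy <- g(x)
  det <- 1 - rho^2
  dens <- outer(x, x, function(a, b) {
    exp(-(a^2 - 2 * rho * a * b + b^2) / (2 * det)) / (2 * pi * sqrt(det))
  })
  as.numeric(t(fx * w) %*% dens %*% (gy * w))
}

# (1/k!) Int_0^Inf x He_k(x) phi(x) dx by adaptive quadrature, with He_k
# written out directly from the recurrence (no package call)
ak_quadrature <- function(k) {
  he <- function(n, z) {
    if (n == 0L) return(rep(1, length(z)))
    if (n == 1L) return(z)
    hm2 <- rep(1, length(z)); hm1 <- z
    for (i in 2:n) {
      h <- z * hm1 - (i - 1) * hm2
      hm2 <- hm1; hm1 <- h
    }
    hm1
  }
  stats::integrate(function(x) x * he(k, x) * stats::dnorm(x), 0, 40,
                   rel.tol = 1e-12)$value / factorial(k)
}

# derivatives of an analytic function at 0 from a degree-8 polynomial fit on
# a symmetric 9-point stencil (accurate to ~h^6 for the third derivative)
poly_derivatives_at_zero <- function(fun, h = 0.04, orders = 1:3) {
  rg <- h * seq(-4, 4)
  y <- vapply(rg, fun, numeric(1L))
  cf <- stats::coef(stats::lm(y ~ stats::poly(rg, 8, raw = TRUE)))
  vapply(orders, function(k) unname(cf[k + 1L]) * factorial(k), numeric(1L))
}

# standard bivariate normal density at (x1, x2) with covariance matrix S,
# evaluated through solve() as an independent route
dens2_oracle <- function(x, S) {
  q <- as.numeric(t(x) %*% solve(S, x))
  exp(-q / 2) / (2 * pi * sqrt(det(S)))
}

# default kernels reused across files
k_sech20 <- make_kernel("sech", tau_s = 20)
k_sech1 <- make_kernel("sech", tau_s = 1)
k_gauss1 <- make_kernel("gaussian", tau_s = 1)
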