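test_that("Rice rate has the closed form and its monotonicity", {
  # psi = 0, unit variance, tau_s = 1: nu = 1/(2 pi) per ms
  expect_equal(rice_rate(1, k_sech1, 0, units = "per_ms"), 1 / (2 * pi))
  expect_equal(rice_rate(1, k_sech1, 0), 1000 / (2 * pi))
  psis <- seq(0, 3, by = 0.5)
  nus <- rice_rate(1, k_sech1, psis)
  expect_true(all(diff(nus) < 0))
  expect_equal(rice_rate(1, k_sech1, -psis), nus)  # even in psi
  expect_true(all(nus > 0))
})

test_that("regression coefficients solve the 2x2 normal equations", {
  p <- process_pair(1, 1, 0.5, 0.7, k_sech1)
  for (tt in c(0.3, 1, -2)) {
    rc <- regression_coefficients(p, tt)
    S <- covariance_matrix(p, tt)$matrix
    # V1' on (V1, V2(tau)): coefficients from the linear solve oracle
    ab <- solve(S[c(1, 3), c(1, 3)], S[c(1, 3), 2])
    expect_equal(c(rc$alpha1, rc$alpha2), unname(ab), tolerance = 1e-12)
    bb <- solve(S[c(1, 3), c(1, 3)], S[c(1, 3), 4])
    expect_equal(c(rc$beta1, rc$beta2), unname(bb), tolerance = 1e-12)
    # residual orthogonality: Cov(eps, (V1, V2)) = 0 by construction
    resid_cov <- S[2, c(1, 3)] - c(rc$alpha1, rc$alpha2) %*% S[c(1, 3), c(1, 3)]
    expect_equal(as.numeric(resid_cov), c(0, 0), tolerance = 1e-12)
    # residual second moments from the Schur complement
    Schur <- S[c(2, 4), c(2, 4)] -
      S[c(2, 4), c(1, 3)] %*% solve(S[c(1, 3), c(1, 3)], S[c(1, 3), c(2, 4)])
    expect_equal(rc$sigma_eps1^2, Schur[1, 1], tolerance = 1e-12)
    expect_equal(rc$sigma_eps2^2, Schur[2, 2], tolerance = 1e-12)
    expect_equal(rc$cov_eps, Schur[1, 2], tolerance = 1e-12)
    # Cauchy-Schwarz
    expect_lte(abs(rc$cov_eps), rc$sigma_eps1 * rc$sigma_eps2 + 1e-15)
  }
})

test_that("regression degenerates correctly at zero lag and long lag", {
  p <- process_pair(10, 5, 9.64, 0.8, k_sech20)
  rc0 <- regression_coefficients(p, 0)
  expect_equal(c(rc0$alpha1, rc0$alpha2, rc0$beta1, rc0$beta2), rep(0, 4))
  expect_equal(c(rc0$a, rc0$b), c(0, 0))
  expect_equal(rc0$sigma_eps1, p$sigma_vp1)
  expect_equal(rc0$sigma_eps2, p$sigma_vp2)
  rcL <- regression_coefficients(p, 500)
  expect_lt(abs(rcL$cov_eps), 1e-8)
  expect_lt(abs(rcL$a), 1e-8)
})

test_that("series terms follow the printed structure", {
  p0 <- process_pair(1, 1, 0.5, 0, k_sech1)
  se <- cab_series(p0, 2)
  # r = 0: a = b = 0, cov_eps = 0, only the order-0 term survives
  expect_equal(se$value, dnorm(0)^2 * p0$sigma_vp1 * p0$sigma_vp2)
  expect_equal(se$terms[-1L], rep(0, length(se$terms) - 1L))
  p <- process_pair(1, 1, 0.5, 0.7, k_sech1)
  rc <- regression_coefficients(p, 0.8)
  se <- cab_series(p, 0.8, n_max = 12)
  phib <- function(x) pnorm(x, lower.tail = FALSE)
  expect_equal(se$terms[1L],
               (rc$b * phib(rc$b) - dnorm(rc$b)) *
                 (rc$a * phib(rc$a) - dnorm(rc$a)) *
                 rc$sigma_eps1 * rc$sigma_eps2)
  expect_equal(se$terms[2L], phib(rc$a) * phib(rc$b) * rc$cov_eps)
  n <- 5
  expect_equal(se$terms[n + 1L],
               dnorm(rc$a) * dnorm(rc$b) *
                 hermite_poly(n - 2, rc$a) * hermite_poly(n - 2, rc$b) *
                 rc$cov_eps^n /
                 (factorial(n) * (rc$sigma_eps1 * rc$sigma_eps2)^(n - 1)))
  expect_lt(se$ratio, 1)
})

test_that("low truncation orders already approximate the converged series", {
  p <- process_pair(10, 10, 9.64, 0.7, k_sech20)
  tg <- seq(-60, 60, by = 10)
  n1 <- nu_cond(p, tg, n_max = 1)
  n10 <- nu_cond(p, tg, n_max = 10)
  n30 <- nu_cond(p, tg, n_max = 30)
  expect_equal(n10, n30, tolerance = 1e-4)   # n = 10 is effectively converged
  expect_equal(n1, n30, tolerance = 0.05)    # n = 1 is already close
})

test_that("conditional rate is 1 under independence and at long lags", {
  p0 <- process_pair(10, 5, 9.64, 0, k_sech20)
  expect_equal(nu_cond(p0, c(-40, 0, 15, 80)), rep(1, 4), tolerance = 1e-12)
  p <- process_pair(10, 5, 9.64, 0.8, k_sech20)
  expect_lt(abs(nu_cond(p, 10 * 20) - 1), 1e-3)
  expect_lt(abs(nu_cond(p, -10 * 20) - 1), 1e-3)
  pg <- process_pair(1, 2, 1, 0.6, k_gauss1)
  expect_lt(abs(nu_cond(pg, 10) - 1), 1e-3)
})

test_that("conditional rate is even in the lag exactly for equal variances", {
  tg <- c(5, 10, 20, 40)
  p_eq <- process_pair(10, 10, 9.64, 0.7, k_sech20)
  expect_equal(nu_cond(p_eq, tg), nu_cond(p_eq, -tg), tolerance = 1e-10)
  p_ne <- process_pair(10, 5, 9.64, 0.7, k_sech20)
  d <- nu_cond(p_ne, tg) - nu_cond(p_ne, -tg)
  expect_gt(max(abs(d)), 0.01)  # clearly asymmetric
})

test_that("series, quadrature oracle and zero-lag closed form agree", {
  for (r in c(0.2, 0.6)) {
    for (sig2 in c(10, 5)) {
      p <- process_pair(10, sig2, 9.64, r, k_sech20)
      for (tt in c(0, 10, 30)) {
        s <- nu_cond(p, tt, n_max = 30)
        o <- nu_cond_oracle(p, tt)
        expect_lt(abs(s - o) / o, 1e-3)
      }
      expect_lt(abs(nu_cond_zero_lag(p) - nu_cond_oracle(p, 0)) /
                  nu_cond_zero_lag(p), 1e-4)
    }
  }
})

test_that("zero-lag value is exactly 1 at r = 0 and continuous in the lag", {
  for (sig2 in c(10, 5)) {
    p0 <- process_pair(10, sig2, 9.64, 0, k_sech20)
    expect_identical(nu_cond_zero_lag(p0), 1)
  }
  p <- process_pair(10, 5, 9.64, 0.7, k_sech20)
  expect_equal(nu_cond(p, 1e-3 * 20, n_max = 200), nu_cond_zero_lag(p),
               tolerance = 1e-2)
})

test_that("Taylor expansion reduces to the Rice rate at r = 0", {
  p <- process_pair(10, 10, 9.64, 0, k_sech20)
  nu <- rice_rate(10, k_sech20, 9.64, units = "per_ms")
  expect_equal(nu_cond_taylor(p, c(5, 20), order = 3), rep(nu, 2))
  p_ne <- process_pair(10, 5, 9.64, 0.3, k_sech20)
  expect_error(nu_cond_taylor(p_ne, 5), "identical pair")
})

test_that("first-order Taylor bracket matches the finite-difference slope", {
  nu <- rice_rate(10, k_sech20, 9.64, units = "per_ms")
  tt <- 20
  # central difference of the full series in r, h = 1e-4
  h <- 1e-4
  g <- function(r) {
    spike_cross_correlation(process_pair(10, 10, 9.64, r, k_sech20), tt,
                            n_max = 60) / nu
  }
  slope <- (g(h) - g(-h)) / (2 * h)
  T1 <- (nu_cond_taylor(process_pair(10, 10, 9.64, 0.5, k_sech20), tt, 1) / nu - 1) / 0.5
  expect_equal(slope / nu, T1, tolerance = 1e-6)
})

test_that("quadrature oracle reduces to 1 under independence", {
  p0 <- process_pair(3, 7, 2, 0, k_gauss1)
  expect_equal(nu_cond_oracle(p0, c(0, 0.5, 2)), rep(1, 3), tolerance = 1e-9)
})

test_that("classical count-variance oracle behaves sensibly", {
  v_inf <- count_variance_rice(0.3, k_sech1)
  v_T <- count_variance_rice(0.3, k_sech1, bin_T = 50)
  expect_gt(v_inf, 0)
  expect_gt(v_T, 0)
  # finite-bin and asymptotic values differ by the O(1/T) boundary term only
  expect_equal(v_T, v_inf, tolerance = 0.1)
})
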