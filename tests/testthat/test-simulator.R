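make_cfg <- function(pair, duration, n_real, seed, ...) {
  suppressWarnings(simulation_config(pair, duration = duration,
                                     n_realizations = n_real, seed = seed,
                                     ...))
}

test_that("generation is bit-reproducible given seed and config", {
  p <- process_pair(10, 10, 9.64, 0.7, k_sech20)
  cfg <- make_cfg(p, 2000, 10, seed = 11)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a$v1, b$v1)
  expect_identical(a$v2, b$v2)
  sa <- simulate_spike_trains(cfg)
  sb <- simulate_spike_trains(cfg)
  expect_identical(sa$trains1, sb$trains1)
  expect_identical(sa$trains2, sb$trains2)
})

test_that("r sweeps reuse the same underlying noise streams", {
  p0 <- process_pair(1, 1, 0.3, 0, k_sech1)
  a <- simulate_pair(make_cfg(p0, 50, 4, seed = 3))
  b <- simulate_pair(make_cfg(p0, 50, 4, seed = 3, r = 0.5))
  # the private components are identical draws; only the mixture changes
  expect_false(identical(a$v1, b$v1))
  expect_gt(cor(as.vector(a$v1), as.vector(b$v1)), 0.5)
})

test_that("r = 1 produces identical normalized paths", {
  p <- process_pair(10, 5, 9.64, 0.7, k_sech20)
  sim <- simulate_pair(make_cfg(p, 2000, 4, seed = 2, r = 1))
  expect_equal(sim$v1 / 10, sim$v2 / 5, tolerance = 1e-12)
})

test_that("sample auto- and cross-covariances match the model", {
  p <- process_pair(10, 5, 9.64, 0.5, k_sech20)
  cfg <- make_cfg(p, 20000, 60, seed = 7, dt = 0.5)
  sim <- simulate_pair(cfg)
  n <- nrow(sim$v1)
  lag <- round(20 / 0.5)  # one correlation time
  per_real_ac <- vapply(seq_len(ncol(sim$v1)), function(j) {
    v <- sim$v1[, j]
    mean(v[1:(n - lag)] * v[(lag + 1):n])
  }, numeric(1))
  target <- 100 * kernel_eval(k_sech20, 20)
  se <- sd(per_real_ac) / sqrt(length(per_real_ac))
  expect_lt(abs(mean(per_real_ac) - target), 4 * se)
  # lag-0 cross covariance r s1 s2
  per_real_cc <- vapply(seq_len(ncol(sim$v1)), function(j) {
    mean(sim$v1[, j] * sim$v2[, j])
  }, numeric(1))
  se <- sd(per_real_cc) / sqrt(length(per_real_cc))
  expect_lt(abs(mean(per_real_cc) - 0.5 * 50), 4 * se)
  # independent channels decorrelate
  sim0 <- simulate_pair(make_cfg(p, 20000, 60, seed = 7, dt = 0.5, r = 0))
  cc0 <- cor(as.vector(sim0$v1), as.vector(sim0$v2))
  expect_lt(abs(cc0), 3 / sqrt(60 * 20000 / 20))  # ~effective sample size
})

test_that("upcrossing detection is exact on deterministic paths", {
  dt <- 0.01
  expect_length(detect_upcrossings(rep(0.5, 1000), 1, dt)$times, 0)
  # sine of amplitude 2 psi over k periods: exactly k upcrossings
  k <- 7
  t <- seq(0, k, by = 1e-3)[-1]
  v <- 2 * sin(2 * pi * t)
  st <- detect_upcrossings(c(0, v), 1, 1e-3)
  expect_length(st$times, k)
  expect_true(all(diff(st$times) > 0))
  expect_true(all(st$times > 0 & st$times <= st$duration))
  # interpolated crossing time of a straight line through the threshold
  st <- detect_upcrossings(c(0, 2), 1, 1)
  expect_equal(st$times, 0.5)
})

test_that("empirical crossing rates match the Rice rate", {
  for (psi_over_s in c(0, 0.964, 1.928)) {
    p <- process_pair(10, 10, 10 * psi_over_s, 0, k_sech20)
    cfg <- make_cfg(p, 20000, 40, seed = 13)
    sim <- simulate_spike_trains(cfg)
    counts <- lengths(lapply(sim$trains1, `[[`, "times"))
    target <- rice_rate(10, k_sech20, 10 * psi_over_s, "per_ms") * 20000
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - target), 3.5 * se + 0.01 * target)
  }
})

test_that("halving dt does not change crossing counts materially", {
  p <- process_pair(10, 10, 9.64, 0, k_sech20)
  counts_at <- function(dt, seed) {
    lengths(lapply(
      simulate_spike_trains(make_cfg(p, 20000, 40, seed = seed,
                                     dt = dt))$trains1,
      `[[`, "times"))
  }
  c1 <- counts_at(0.4, seed = 5)
  c2 <- counts_at(0.2, seed = 6)
  se <- sqrt(var(c1) / length(c1) + var(c2) / length(c2))
  target <- rice_rate(10, k_sech20, 9.64, "per_ms") * 20000
  # the two discretizations agree within Monte Carlo error plus a small
  # O(dt^2) allowance, and neither is materially biased against the Rice rate
  expect_lt(abs(mean(c1) - mean(c2)), 3 * se + 0.01 * target)
  expect_lt(abs(mean(c2) - target), 3 * sd(c2) / sqrt(length(c2)) +
              0.005 * target)
})

test_that("count binning follows the half-open convention and centering", {
  tr <- function(times, dur) {
    structure(list(times = times, duration = dur, threshold = 1),
              class = "spike_train")
  }
  tab <- bin_counts(list(tr(c(1, 2, 3), 25)), list(tr(numeric(0), 25)),
                    bin_T = 10)
  expect_equal(nrow(tab$raw), 2L)      # the 5 ms edge bin is discarded
  expect_equal(tab$raw[, "n1"], c(3L, 0L))
  expect_equal(tab$raw[, "n2"], c(0L, 0L))
  expect_equal(colMeans(tab$normalized), c(n1 = 0, n2 = 0))
  # a count exactly on a bin edge belongs to the right bin
  tab2 <- bin_counts(list(tr(10, 20)), list(tr(9.999, 20)), bin_T = 10)
  expect_equal(tab2$raw[, "n1"], c(0L, 1L))
  expect_equal(tab2$raw[, "n2"], c(1L, 0L))
  expect_error(bin_counts(list(tr(1, 5)), list(tr(1, 5)), bin_T = 10),
               "exceeds")
})

test_that("empirical conditional rate is flat at 1 for independent trains", {
  p <- process_pair(10, 10, 9.64, 0, k_sech20)
  sim <- simulate_spike_trains(make_cfg(p, 20000, 300, seed = 21))
  est <- empirical_nucond(sim$trains1, sim$trains2,
                          tau_grid = seq(-40, 40, by = 20), corr_bin = 8)
  expect_true(all(abs(est$nucond - 1) < 4 * est$se))
})

test_that("empirical conditional rate recovers the series prediction", {
  p <- process_pair(10, 10, 9.64, 0.7, k_sech20)
  sim <- simulate_spike_trains(make_cfg(p, 20000, 400, seed = 23))
  tg <- c(-40, -20, 0, 20, 40)
  est <- empirical_nucond(sim$trains1, sim$trains2, tau_grid = tg,
                          corr_bin = 4)
  theory <- nu_cond(p, tg, n_max = 10)
  expect_true(all(abs(est$nucond - theory) < 4 * est$se + 0.02 * theory))
})

test_that("count covariance estimator matches construction cases", {
  p <- process_pair(10, 10, 9.64, 0, k_sech20)
  sim <- simulate_spike_trains(make_cfg(p, 20000, 200, seed = 31))
  tab <- bin_counts(sim$trains1, sim$trains2, bin_T = 1000, time_scale = 20)
  cc <- empirical_count_covariance(tab)
  expect_equal(cc, t(cc))
  expect_true(all(diag(cc) > 0))
  expect_lt(abs(cc[1, 2]), 3 * attr(cc, "se")[1, 2])
  # duplicated channel: off-diagonal equals the diagonal
  tab2 <- bin_counts(sim$trains1, sim$trains1, bin_T = 1000, time_scale = 20)
  cc2 <- empirical_count_covariance(tab2)
  expect_equal(cc2[1, 2], cc2[1, 1])
})

test_that("simulated count variance matches the classical oracle", {
  # unit-variance rescaled process, psi = 0.3: long bins reproduce the
  # finite-bin Rice-formula variance
  p <- process_pair(1, 1, 0.3, 0, k_sech1)
  sim <- simulate_spike_trains(make_cfg(p, 50, 1500, seed = 41, dt = 0.02,
                                        bin_T = 50))
  tab <- bin_counts(sim$trains1, sim$trains2, bin_T = 50, time_scale = 1)
  cc <- empirical_count_covariance(tab)
  target <- count_variance_rice(0.3, k_sech1, bin_T = 50)
  expect_lt(abs(cc[1, 1] - target), 3 * attr(cc, "se")[1, 1])
})
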