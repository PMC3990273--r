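#' Simulation configuration for a correlated voltage pair
#'
#' Bundles a [process_pair()] with the discretization and replication
#' parameters of the simulator. The correlation strength used for the
#' shared/private noise mixture defaults to the pair's `r` but may be
#' overridden, and `r = 1` (purely shared noise, identical normalized paths)
#' is allowed here as a limiting diagnostic even though the analytic pair
#' excludes it.
#'
#' @param pair A [process_pair()].
#' @param duration Length of each realization (ms).
#' @param n_realizations Number of independent realizations.
#' @param seed Integer seed; mandatory, every random draw derives from it.
#' @param dt Sample step (ms); default `tau_s / 50`. A warning is issued
#'   above `tau_s / 20`, where discretization bias in crossing detection
#'   becomes noticeable.
#' @param bin_T Count bin (ms); default `20 tau_s`. A warning is issued when
#'   `duration < 10 bin_T`.
#' @param r Mixing correlation in `[0, 1]`; default `pair$r`.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(pair, duration, n_realizations, seed,
                              dt = NULL, bin_T = NULL, r = NULL) {
  stopifnot(inherits(pair, "process_pair"))
  ts <- pair$kernel$tau_s
  if (is.null(dt)) dt <- ts / 50
  if (is.null(bin_T)) bin_T <- 20 * ts
  if (is.null(r)) r <- pair$r
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' is mandatory (integer)")
  }
  if (dt <= 0 || duration <= 0 || n_realizations < 1) {
    stop("'dt', 'duration' must be positive and 'n_realizations' >= 1")
  }
  if (r < 0 || r > 1) stop("simulation mixing 'r' must lie in [0, 1]")
  if (dt > ts / 20) {
    warning(sprintf("dt = %g ms exceeds tau_s/20 = %g ms: crossing counts will be biased low",
                    dt, ts / 20))
  }
  if (duration < 10 * bin_T) {
    warning("duration < 10 * bin_T: few complete count bins per realization")
  }
  structure(list(pair = pair, dt = dt, duration = duration,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), bin_T = bin_T, r = r),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> N = %d x %g ms, dt = %g ms, bin_T = %g ms, r = %g, seed = %d\n",
    x$n_realizations, x$duration, x$dt, x$bin_T, x$r, x$seed))
  invisible(x)
}

# --- RNG sub-streams -------------------------------------------------------
# three independent generating paths (two private, one shared) consume three
# sub-streams derived from the master seed, so that sweeping r reuses the
# same underlying noise (variance reduction for r sweeps)

rng_streams <- function(seed, k = 3L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, k)
  states <- vector("list", k)
  for (j in seq_len(k)) {
    set.seed(sub[j])
    states[[j]] <- get(".Random.seed", envir = globalenv())
  }
  env <- new.env(parent = emptyenv())
  env$states <- states
  env
}

stream_rnorm <- function(streams, j, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", streams$states[[j]], envir = globalenv())
  x <- stats::rnorm(n)
  streams$states[[j]] <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  x
}

# --- circulant embedding ---------------------------------------------------

# eigenvalues of the circulant embedding of the covariance sequence c(k dt),
# k = 0..n-1; negative eigenvalues below round-off are clipped, larger
# deficits trigger a warning (the grid is then enlarged by the caller)
circulant_eigenvalues <- function(kernel, dt, n) {
  m <- 2L^ceiling(log2(max(2L * (n - 1L), 2L)))
  lags <- dt * 0:(m / 2L)
  cv <- kernel$c0(lags)
  g <- c(cv, rev(cv[2:(m / 2L)]))
  lam <- Re(stats::fft(g))
  mn <- min(lam)
  if (mn < -1e-8 * max(lam)) {
    warning(sprintf(
      "circulant embedding not PSD (min eigenvalue %.3g): clipping to zero", mn))
  }
  lam[lam < 0] <- 0
  list(lam = lam, m = m)
}

# 2*ncols unit-variance stationary paths of length n, via FFT of the
# eigenvalue-scaled complex white noise; real and imaginary parts are
# independent
paths_from_eigs <- function(emb, n, ncols, streams, j) {
  m <- emb$m
  z <- stream_rnorm(streams, j, 2L * m * ncols)
  xi <- matrix(complex(real = z[seq_len(m * ncols)],
                       imaginary = z[m * ncols + seq_len(m * ncols)]),
               nrow = m, ncol = ncols)
  y <- stats::mvfft(sqrt(emb$lam) * xi) / sqrt(m)
  cbind(Re(y[seq_len(n), , drop = FALSE]), Im(y[seq_len(n), , drop = FALSE]))
}

#' Simulate a correlated stationary Gaussian voltage pair
#'
#' Exact-in-distribution synthesis of the bivariate model: three independent
#' unit-variance stationary paths `Z1`, `Z2`, `Zc` with the pair's kernel are
#' generated by circulant embedding of the covariance sequence, and combined
#' as `V1 = sigma_v1 (sqrt(1-r) Z1 + sqrt(r) Zc)`,
#' `V2 = sigma_v2 (sqrt(1-r) Z2 + sqrt(r) Zc)`. Generation is
#' bit-reproducible given `(seed, config)` and the three paths consume
#' separate sub-streams, so sweeping `r` holds the underlying noise fixed.
#'
#' This function materializes full voltage matrices and is intended for
#' moderate problem sizes; use [simulate_spike_trains()] for large
#' replication counts, which batches the synthesis and retains only crossing
#' times.
#'
#' @param config A [simulation_config()].
#' @return List with `time` (sample times, ms), matrices `v1`, `v2`
#'   (`n_samples x n_realizations`, mV) and the `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- floor(config$duration / config$dt) + 1L
  emb <- circulant_eigenvalues(config$pair$kernel, config$dt, n)
  streams <- rng_streams(config$seed)
  ncols <- ceiling(config$n_realizations / 2L)
  z1 <- paths_from_eigs(emb, n, ncols, streams, 1L)
  z2 <- paths_from_eigs(emb, n, ncols, streams, 2L)
  zc <- paths_from_eigs(emb, n, ncols, streams, 3L)
  keep <- seq_len(config$n_realizations)
  r <- config$r
  v1 <- config$pair$sigma_v1 * (sqrt(1 - r) * z1[, keep, drop = FALSE] +
                                  sqrt(r) * zc[, keep, drop = FALSE])
  v2 <- config$pair$sigma_v2 * (sqrt(1 - r) * z2[, keep, drop = FALSE] +
                                  sqrt(r) * zc[, keep, drop = FALSE])
  list(time = config$dt * (seq_len(n) - 1L), v1 = v1, v2 = v2,
       config = config)
}

#' Detect threshold upcrossings in a sampled path
#'
#' One crossing is registered for every index `i` with
#' `v[i] < psi <= v[i+1]` (strict below / at-or-above convention, so
#' tangential touches count once); the crossing time is linearly interpolated
#' within the step. Crossings missed between samples scale as `O(dt^2)` for
#' twice-differentiable kernels.
#'
#' @param v Numeric vector of uniformly sampled voltage values (mV).
#' @param psi Threshold (mV).
#' @param dt Sample step (ms).
#' @return Object of class `spike_train`: `times` (ms, strictly increasing,
#'   in `(0, duration]`), `duration`, `threshold`.
#' @export
detect_upcrossings <- function(v, psi, dt) {
  if (length(v) < 2L) stop("path must contain at least two samples")
  n <- length(v)
  idx <- which(v[-n] < psi & v[-1L] >= psi)
  frac <- (psi - v[idx]) / (v[idx + 1L] - v[idx])
  structure(list(times = (idx - 1L + frac) * dt,
                 duration = (n - 1L) * dt, threshold = psi),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d crossings of %g mV in %g ms (rate %.4g Hz)\n",
              length(x$times), x$threshold, x$duration,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Simulate spike trains of a correlated voltage pair
#'
#' Batched synthesis (see [simulate_pair()]) followed by upcrossing
#' detection; only the crossing times are kept, so large replication counts
#' fit in memory. Bit-reproducible given `(seed, config)`.
#'
#' @param config A [simulation_config()].
#' @param batch_cols Number of FFT columns per batch (each column yields two
#'   realizations).
#' @return List with `trains1`, `trains2` (lists of [detect_upcrossings()]
#'   spike trains, one per realization) and the `config`.
#' @export
simulate_spike_trains <- function(config, batch_cols = 64L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- floor(config$duration / config$dt) + 1L
  emb <- circulant_eigenvalues(config$pair$kernel, config$dt, n)
  streams <- rng_streams(config$seed)
  N <- config$n_realizations
  r <- config$r
  psi <- config$pair$psi
  trains1 <- vector("list", N)
  trains2 <- vector("list", N)
  done <- 0L
  while (done < N) {
    nb <- min(batch_cols, ceiling((N - done) / 2L))
    z1 <- paths_from_eigs(emb, n, nb, streams, 1L)
    z2 <- paths_from_eigs(emb, n, nb, streams, 2L)
    zc <- paths_from_eigs(emb, n, nb, streams, 3L)
    take <- min(2L * nb, N - done)
    for (j in seq_len(take)) {
      v1 <- config$pair$sigma_v1 * (sqrt(1 - r) * z1[, j] + sqrt(r) * zc[, j])
      v2 <- config$pair$sigma_v2 * (sqrt(1 - r) * z2[, j] + sqrt(r) * zc[, j])
      trains1[[done + j]] <- detect_upcrossings(v1, psi, config$dt)
      trains2[[done + j]] <- detect_upcrossings(v2, psi, config$dt)
    }
    done <- done + take
  }
  list(trains1 = trains1, trains2 = trains2, config = config)
}

#' Bin spike counts of paired trains
#'
#' Raw upcrossing counts of both channels in half-open bins
#' `[k T, (k+1) T)`; edge bins shorter than `T` are discarded. The
#' normalized deviations divide the centered counts by
#' `sqrt(bin_T / time_scale)`, i.e. the bin length is measured in units of
#' the correlation time, matching the normalization under which the
#' asymptotic count covariances `a11`, `a22`, `a12` are stated.
#'
#' @param trains1,trains2 Lists of [detect_upcrossings()] spike trains of
#'   equal length (matched realizations).
#' @param bin_T Bin length (ms); must not exceed the realization duration.
#' @param time_scale Time unit for the normalization (ms); use the pair's
#'   `tau_s` (default 1, i.e. bins already in rescaled units).
#' @return Object of class `count_table`: `raw` (`n_bins_total x 2` integer
#'   counts), `normalized` (same shape, centered and scaled),
#'   `realization` (origin of each row), `bin_T`, `time_scale`.
#' @export
bin_counts <- function(trains1, trains2, bin_T, time_scale = 1) {
  if (length(trains1) != length(trains2)) {
    stop("matched realization counts required")
  }
  dur <- trains1[[1L]]$duration
  if (bin_T > dur) stop("'bin_T' exceeds the realization duration")
  nb <- floor(dur / bin_T)
  counts_of <- function(tr) {
    idx <- floor(tr$times / bin_T) + 1L
    tabulate(idx[idx <= nb], nbins = nb)
  }
  raw1 <- unlist(lapply(trains1, counts_of))
  raw2 <- unlist(lapply(trains2, counts_of))
  raw <- cbind(n1 = raw1, n2 = raw2)
  normalized <- sweep(raw, 2L, colMeans(raw)) / sqrt(bin_T / time_scale)
  structure(list(raw = raw, normalized = normalized,
                 realization = rep(seq_along(trains1), each = nb),
                 bin_T = bin_T, time_scale = time_scale),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d bins of %g ms from %d realizations; mean counts (%.3g, %.3g)\n",
              nrow(x$raw), x$bin_T, max(x$realization),
              mean(x$raw[, 1L]), mean(x$raw[, 2L])))
  invisible(x)
}

#' Cross-correlogram estimate of the conditional rate
#'
#' Histogram of pairwise crossing-time differences `t2 - t1` in bins of
#' width `corr_bin` centered on `tau_grid`, normalized per realization by
#' `nu1 nu2 * corr_bin * (duration - |tau|)` so that the estimate is 1 for
#' independent trains. Returns the across-realization mean and standard
#' error per lag.
#'
#' @param trains1,trains2 Matched lists of spike trains.
#' @param tau_grid Lag centers (ms); bins must not overlap
#'   (`min(diff(tau_grid)) >= corr_bin`).
#' @param corr_bin Correlogram bin width (ms), small against `tau_s`.
#' @param rates Optional length-2 vector of rates in 1/ms used for the
#'   normalization; defaults to the pooled empirical rates.
#' @return Data frame with columns `tau`, `nucond`, `se`, `n_pairs`.
#' @export
empirical_nucond <- function(trains1, trains2, tau_grid, corr_bin,
                             rates = NULL) {
  if (length(trains1) != length(trains2)) {
    stop("matched realization counts required")
  }
  if (length(tau_grid) > 1L && min(diff(sort(tau_grid))) < corr_bin) {
    stop("'tau_grid' spacing must be at least 'corr_bin'")
  }
  dur <- trains1[[1L]]$duration
  N <- length(trains1)
  if (is.null(rates)) {
    rates <- c(sum(lengths(lapply(trains1, `[[`, "times"))),
               sum(lengths(lapply(trains2, `[[`, "times")))) / (N * dur)
  }
  if (any(rates <= 0)) stop("zero crossing rate: cannot normalize")
  ord <- order(tau_grid)
  tg <- tau_grid[ord]
  lo <- tg - corr_bin / 2
  hi <- tg + corr_bin / 2
  per_real <- matrix(0, nrow = N, ncol = length(tg))
  win <- max(abs(c(lo, hi)))
  for (i in seq_len(N)) {
    t1 <- trains1[[i]]$times
    t2 <- trains2[[i]]$times
    if (!length(t1) || !length(t2)) next
    d <- as.vector(outer(t2, t1, "-"))
    d <- d[abs(d) <= win]
    if (!length(d)) next
    cnt <- vapply(seq_along(tg),
                  function(j) sum(d >= lo[j] & d < hi[j]), numeric(1L))
    per_real[i, ] <- cnt / (corr_bin * (dur - abs(tg)) * rates[1L] * rates[2L])
  }
  est <- colMeans(per_real)
  se <- apply(per_real, 2L, stats::sd) / sqrt(N)
  data.frame(tau = tg, nucond = est, se = se)
}

#' Sample covariance of normalized spike counts
#'
#' Unbiased 2x2 sample covariance of the normalized count columns of a
#' [bin_counts()] table, with large-sample standard errors
#' (`var_jj sqrt(2/(n-1))` for the diagonal,
#' `sqrt((var_11 var_22 + cov^2)/(n-1))` for the off-diagonal) attached as
#' attribute `se`.
#'
#' @param table A `count_table`.
#' @return Symmetric 2x2 covariance matrix with attributes `se` and `n`.
#' @export
empirical_count_covariance <- function(table) {
  stopifnot(inherits(table, "count_table"))
  n <- nrow(table$normalized)
  if (n < 2L) stop("at least two bins required")
  S <- stats::cov(table$normalized)
  se <- matrix(c(S[1L, 1L] * sqrt(2 / (n - 1)),
                 sqrt((S[1L, 1L] * S[2L, 2L] + S[1L, 2L]^2) / (n - 1)),
                 sqrt((S[1L, 1L] * S[2L, 2L] + S[1L, 2L]^2) / (n - 1)),
                 S[2L, 2L] * sqrt(2 / (n - 1))), 2L)
  attr(S, "se") <- se
  attr(S, "n") <- n
  S
}
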