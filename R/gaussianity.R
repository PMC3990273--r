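#' Projection normality test battery
#'
#' Tests joint Gaussianity of a bivariate count sample by checking that every
#' univariate projection is Gaussian: for each direction
#' `(cos(theta), sin(theta))` on a deterministic uniform grid over
#' `[0, 2 pi)`, the Shapiro-Wilk test is applied to the projected sample and
#' the p-value recorded. A multivariate normal vector has normal projections
#' in every direction, while marginally-normal-but-jointly-non-normal
#' counterexamples fail in some direction.
#'
#' Shapiro-Wilk is validated for sample sizes up to 5000; larger samples are
#' reduced by a fixed-seed subsample (the same indices for every direction),
#' which is reported in the output attributes.
#'
#' @param x A [bin_counts()] `count_table` (its normalized columns are used)
#'   or a two-column numeric matrix.
#' @param n_theta Number of directions on the uniform grid (default 64).
#' @param max_n Largest sample size passed to the Shapiro-Wilk test.
#' @param subsample_seed Seed for the fixed subsample when `n > max_n`.
#' @return Data frame with columns `theta`, `p_value`; attributes `min_p`,
#'   `bonferroni_alpha` (0.01 / n_theta) and `subsampled`.
#' @export
projection_normality <- function(x, n_theta = 64L, max_n = 5000L,
                                 subsample_seed = 1L) {
  X <- if (inherits(x, "count_table")) x$normalized else as.matrix(x)
  if (ncol(X) != 2L) stop("a bivariate sample is required")
  n <- nrow(X)
  idx <- seq_len(n)
  subsampled <- FALSE
  if (n > max_n) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(subsample_seed)
    idx <- sample.int(n, max_n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    subsampled <- TRUE
  }
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  p <- vapply(theta, function(th) {
    a <- X[idx, 1L] * cos(th) + X[idx, 2L] * sin(th)
    if (stats::sd(a) == 0) stop("degenerate (constant) projection")
    stats::shapiro.test(a)$p.value
  }, numeric(1L))
  out <- data.frame(theta = theta, p_value = p)
  attr(out, "min_p") <- min(p)
  attr(out, "bonferroni_alpha") <- 0.01 / n_theta
  attr(out, "subsampled") <- subsampled
  out
}

#' Mahalanobis distance test against the chi-squared law
#'
#' Under bivariate normality the squared Mahalanobis distances
#' `D_i^2 = (X_i - mu)' Sigma^{-1} (X_i - mu)`, with `mu` and `Sigma`
#' estimated from the same sample (plug-in), follow a chi-squared law with 2
#' degrees of freedom. Returns the distances, their mean (close to 2 under
#' normality), a Kolmogorov-Smirnov comparison with the chi-squared
#' reference, and QQ quantile pairs for plotting.
#'
#' @param x A `count_table` or two-column numeric matrix.
#' @param n_qq Number of QQ quantile pairs.
#' @return Object of class `normality_report`: `d2`, `mean_d2`, `se_mean`
#'   (standard error of the mean under the chi-squared law), `ks_stat`,
#'   `ks_p`, and `qq` (data frame `theoretical`, `empirical`, sorted).
#' @export
mahalanobis_chi2 <- function(x, n_qq = 200L) {
  X <- if (inherits(x, "count_table")) x$normalized else as.matrix(x)
  if (ncol(X) != 2L) stop("a bivariate sample is required")
  S <- stats::cov(X)
  if (!is.finite(determinant(S)$modulus) || det(S) <= 0) {
    stop("singular estimated covariance")
  }
  d2 <- stats::mahalanobis(X, colMeans(X), S)
  ks <- suppressWarnings(stats::ks.test(d2, stats::pchisq, df = 2))
  probs <- (seq_len(n_qq) - 0.5) / n_qq
  qq <- data.frame(theoretical = stats::qchisq(probs, df = 2),
                   empirical = unname(stats::quantile(d2, probs)))
  structure(list(d2 = d2, mean_d2 = mean(d2),
                 se_mean = 2 / sqrt(length(d2)),  # sd of chi^2_2 is 2
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value, qq = qq),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> mean D^2 = %.4f (expect 2 +- %.3f), KS = %.4f (p = %.3g)\n",
              x$mean_d2, x$se_mean, x$ks_stat, x$ks_p))
  invisible(x)
}

#' Combined joint-Gaussianity battery
#'
#' Runs [projection_normality()] and [mahalanobis_chi2()] on a bivariate
#' count sample and summarizes the verdict: minimum projection p-value, its
#' Bonferroni-adjusted comparison with the 1% level (reported, not
#' enforced), and the Mahalanobis summary.
#'
#' @inheritParams projection_normality
#' @return List with `projections`, `mahalanobis`, `min_p`,
#'   `reject_bonferroni_1pct`.
#' @export
gaussianity_battery <- function(x, n_theta = 64L, max_n = 5000L,
                                subsample_seed = 1L) {
  proj <- projection_normality(x, n_theta = n_theta, max_n = max_n,
                               subsample_seed = subsample_seed)
  maha <- mahalanobis_chi2(x)
  list(projections = proj, mahalanobis = maha,
       min_p = attr(proj, "min_p"),
       reject_bonferroni_1pct = attr(proj, "min_p") < 0.01 / n_theta)
}
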