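#' Bland–Altman agreement statistics for paired ICP readings
#'
#' Differences are taken as invasive minus non-invasive. Reports the mean
#' difference (bias), the sample standard deviation (n - 1 denominator), the
#' parametric 95% limits of agreement mean +/- 1.96 SD, the empirical
#' 2.5/97.5 percentiles, and the extreme differences.
#'
#' @param icp_inv Invasive ICP readings (mmHg), or a `monitoring_result`
#'   whose pairs are used directly.
#' @param icp_noninv Non-invasive ICP readings (mmHg).
#' @return An object of class `bland_altman` with `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `q025`, `q975`, `min_diff`,
#'   `max_diff` (all mmHg) and the difference vector.
#' @examples
#' ba <- bland_altman(c(10, 12, 14), c(10.5, 11.8, 14.2))
#' ba$loa_low; ba$loa_high
#' @export
bland_altman <- function(icp_inv, icp_noninv = NULL) {
  if (inherits(icp_inv, "monitoring_result")) {
    d <- icp_inv$pairs$diff_mmhg
    means <- (icp_inv$pairs$icp_inv_mmhg + icp_inv$pairs$icp_noninv_mmhg) / 2
  } else {
    if (length(icp_inv) != length(icp_noninv)) stop("paired inputs must have equal length")
    d <- icp_inv - icp_noninv
    means <- (icp_inv + icp_noninv) / 2
  }
  if (length(d) < 2) stop("at least 2 pairs are required")
  m <- mean(d); s <- stats::sd(d)
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(n = length(d), mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         q025 = q[1], q975 = q[2],
         min_diff = min(d), max_diff = max(d),
         differences = d, pair_means = means),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (invasive - non-invasive), n = %d\n", x$n))
  cat(sprintf("  bias %.3f mmHg, SD %.3f mmHg\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement [%.2f, %.2f] mmHg; empirical 95%% [%.2f, %.2f]\n",
              x$loa_low, x$loa_high, x$q025, x$q975))
  cat(sprintf("  extremes [%.2f, %.2f] mmHg\n", x$min_diff, x$max_diff))
  invisible(x)
}

#' Pool per-subject difference summaries across a cohort
#'
#' Combines per-subject (mean, SD, n) difference summaries into the overall
#' mean and standard deviation, using the exact combined-variance identity
#' \deqn{SD^2 = \frac{\sum_i\left[(n_i-1)sd_i^2 + n_i(\bar d_i - \bar d)^2\right]}{N-1}}
#' with \eqn{\bar d = \sum_i n_i \bar d_i / N} and \eqn{N = \sum_i n_i}, so
#' pooling split subsets of one sample reproduces the direct sample
#' statistics to machine precision.
#'
#' @param groups Data frame with columns `mean`, `sd`, `n` (one row per
#'   subject); a `subject` column is carried through if present.
#' @return List with `pooled_mean` (mmHg), `pooled_sd` (mmHg) and `n_total`.
#' @examples
#' pooled_stats(data.frame(mean = c(0.4, -0.2), sd = c(0.9, 1.2), n = c(200, 300)))
#' @export
pooled_stats <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) < 1)
    stop("at least one group summary is required")
  stopifnot(all(c("mean", "sd", "n") %in% names(groups)))
  if (any(groups$n < 2)) stop("each group needs n >= 2")
  if (any(groups$sd < 0)) stop("group SDs must be non-negative")
  N <- sum(groups$n)
  m <- sum(groups$n * groups$mean) / N
  ss <- sum((groups$n - 1) * groups$sd^2 + groups$n * (groups$mean - m)^2)
  list(pooled_mean = m, pooled_sd = sqrt(ss / (N - 1)), n_total = N)
}

#' Agreement regression of non-invasive on invasive ICP
#'
#' Ordinary least squares of the non-invasive estimates on the invasive
#' reference, plus the Pearson correlation — the linearity test for the
#' artery-as-pressure-sensor hypothesis (slope near 1, intercept near 0 and
#' r near 1 indicate a linear, well-calibrated sensor).
#'
#' @param icp_inv Invasive ICP readings (mmHg), or a `monitoring_result`.
#' @param icp_noninv Non-invasive ICP readings (mmHg).
#' @return An object of class `agreement_regression` with `slope`,
#'   `intercept` (mmHg), `r` and `n`.
#' @export
agreement_regression <- function(icp_inv, icp_noninv = NULL) {
  if (inherits(icp_inv, "monitoring_result")) {
    icp_noninv <- icp_inv$pairs$icp_noninv_mmhg
    icp_inv <- icp_inv$pairs$icp_inv_mmhg
  }
  if (length(icp_inv) != length(icp_noninv)) stop("paired inputs must have equal length")
  if (length(icp_inv) < 3) stop("at least 3 pairs are required")
  if (stats::sd(icp_inv) == 0) stop("no variance in the invasive reference")
  fit <- stats::lm(icp_noninv ~ icp_inv)
  cf <- unname(stats::coef(fit))
  structure(
    list(slope = cf[2], intercept = cf[1],
         r = stats::cor(icp_inv, icp_noninv), n = length(icp_inv)),
    class = "agreement_regression"
  )
}

#' @export
print.agreement_regression <- function(x, ...) {
  cat(sprintf("Agreement regression: y = %.3f x + %.3f mmHg, r = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}
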