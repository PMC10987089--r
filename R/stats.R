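# Statistical kernels: Fisher transform, dependent-correlation tests,
# normal-prior Bayes factors, percentile bootstrap.

#' Fisher z transform
#'
#' `arctanh(r)`, the variance-stabilizing transform of a Pearson
#' correlation.
#'
#' @param r Correlation(s) strictly inside (-1, 1).
#' @return Numeric vector of Fisher z values.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    aff_stop("`r` must lie strictly inside (-1, 1)", "domain_error")
  atanh(r)
}

#' Inverse Fisher transform
#' @param z Fisher z value(s).
#' @return Correlations in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Bayes factor for a Fisher-z observation under normal priors
#'
#' Closed-form BF10 for an observed Fisher-z effect with known standard
#' error: the marginal likelihood of `z_obs` under H1 (`N(h1_mean, h1_sd^2)`
#' prior on the effect) divided by that under H0 (`N(h0_mean, h0_sd^2)`).
#' Both marginals are normal, `N(prior mean, se^2 + prior sd^2)`. A BF10
#' above 10 is conventionally read as strong evidence for H1.
#'
#' @param z_obs Observed effect on the Fisher-z scale.
#' @param se Standard error of `z_obs` (> 0; may be 0 for the limit case).
#' @param h0_mean,h0_sd Null prior, default standard normal.
#' @param h1_mean,h1_sd Alternative prior, default `N(2, 1)`.
#' @return BF10, a positive scalar.
#' @export
bayes_factor_normal <- function(z_obs, se, h0_mean = 0, h0_sd = 1,
                                h1_mean = 2, h1_sd = 1) {
  if (!is.finite(z_obs) || !is.finite(se) || se < 0)
    aff_stop("`z_obs` and `se` must be finite, `se` >= 0", "value_error")
  check_scalar_in(h0_sd, "h0_sd", 0, Inf, open_lo = TRUE)
  check_scalar_in(h1_sd, "h1_sd", 0, Inf, open_lo = TRUE)
  s1 <- sqrt(se^2 + h1_sd^2)
  s0 <- sqrt(se^2 + h0_sd^2)
  exp(stats::dnorm(z_obs, h1_mean, s1, log = TRUE) -
        stats::dnorm(z_obs, h0_mean, s0, log = TRUE))
}

#' Steiger's Z for two dependent overlapping correlations
#'
#' Tests H0: rho12 = rho13 when both correlations share variable 1 and are
#' estimated from the same sample of size `n`. Uses Steiger's (1980)
#' modification that plugs the mean correlation into the covariance term of
#' the Fisher-z difference. `Z > 0` when `r12 > r13`; the one-tailed p tests
#' the directional hypothesis rho12 > rho13.
#'
#' @param r12,r13 The two correlations being compared (shared variable 1).
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 4); here, the number of actions.
#' @return List with `Z`, `p_one_tailed`, `p_two_tailed`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (n < 4) aff_stop("`n` must be at least 4", "value_error")
  if (any(abs(c(r12, r13, r23)) >= 1))
    aff_stop("correlations must lie strictly inside (-1, 1) for the Fisher transform",
             "domain_error")
  det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  if (det3 < -1e-12)
    aff_stop("correlation triple is not positive semidefinite", "consistency_error")
  rbar <- (r12 + r13) / 2
  cov_term <- (r23 * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
  Z <- (fisher_z(r12) - fisher_z(r13)) * sqrt((n - 3) / (2 - 2 * cov_term))
  list(Z = Z,
       p_one_tailed = stats::pnorm(Z, lower.tail = FALSE),
       p_two_tailed = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
}

#' Zou's confidence interval for a difference of overlapping correlations
#'
#' Confidence interval for `rho12 - rho13` (shared variable 1) by Zou's
#' (2007) modified asymptotic method: back-transformed Fisher-z limits for
#' each correlation, combined with their asymptotic correlation.
#'
#' @inheritParams steiger_z
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
zou_ci <- function(r12, r13, r23, n, level = 0.95) {
  if (n < 4) aff_stop("`n` must be at least 4", "value_error")
  check_scalar_in(level, "level", 0, 1, open_lo = TRUE, open_hi = TRUE)
  q <- stats::qnorm(1 - (1 - level) / 2)
  lim <- function(r) fisher_z_inv(fisher_z(r) + c(-1, 1) * q / sqrt(n - 3))
  l1u1 <- lim(r12); l2u2 <- lim(r13)
  c_num <- r23 * (1 - r12^2 - r13^2) -
    0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
  corr <- c_num / ((1 - r12^2) * (1 - r13^2))
  diff <- r12 - r13
  lo <- diff - sqrt((r12 - l1u1[1])^2 + (l2u2[2] - r13)^2 -
                      2 * corr * (r12 - l1u1[1]) * (l2u2[2] - r13))
  hi <- diff + sqrt((l1u1[2] - r12)^2 + (r13 - l2u2[1])^2 -
                      2 * corr * (l1u1[2] - r12) * (r13 - l2u2[1]))
  c(lower = lo, upper = hi)
}

#' Percentile bootstrap CI for a mean
#'
#' Seeded percentile bootstrap of the sample mean.
#'
#' @param values Numeric vector (length >= 2).
#' @param level Confidence level in (0, 1).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)`.
#' @export
percentile_bootstrap_ci <- function(values, level = 0.95, n_boot = 1000L,
                                    seed = 1L) {
  if (length(values) < 2L)
    aff_stop("need at least 2 values to bootstrap", "degenerate_input")
  check_scalar_in(level, "level", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_scalar_in(n_boot, "n_boot", 1, Inf)
  n <- length(values)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(values[idx], nrow = n_boot))
  })
  ci <- stats::quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  c(lower = ci[1], upper = ci[2])
}
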