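#' Beta prior constructor
#'
#' A beta prior on penetrance, interpretable as `alpha` hypothetical affected
#' and `beta` hypothetical unaffected heterozygotes.
#'
#' @param alpha Positive shape: hypothetical affected heterozygotes.
#' @param beta Positive shape: hypothetical unaffected heterozygotes.
#' @return An object of class `beta_prior` with elements `alpha` and `beta`.
#' @examples
#' beta_prior(0.45, 2.73)
#' @export
beta_prior <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("beta_prior: 'alpha' and 'beta' must be finite scalars > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta prior: alpha = %.4g, beta = %.4g (mean %.4f, worth %.4g heterozygotes)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta), x$alpha + x$beta))
  invisible(x)
}

#' @export
mean.beta_prior <- function(x, ...) x$alpha / (x$alpha + x$beta)

#' Confidence weight of a variant's heterozygote count
#'
#' The weight `1 - 1/(0.01 + n)` used when pooling observed penetrances into
#' the empirical prior: a variant observed in more heterozygotes carries a
#' more trustworthy penetrance estimate and receives weight approaching 1,
#' while singleton variants get weight just under 0.01.
#'
#' @param n Integer vector of total heterozygote counts, all >= 1.
#' @return Numeric vector of weights in (0.0099, 1), strictly increasing in n.
#' @examples
#' heterozygote_weight(c(1, 10, 100))
#' @export
heterozygote_weight <- function(n) {
  if (length(n) == 0L || any(!is.finite(n)) || any(n < 1))
    stop("heterozygote_weight: all counts must be finite and >= 1", call. = FALSE)
  1 - 1 / (0.01 + n)
}

#' Moment-match a beta distribution to a mean and variance
#'
#' Solves for the unique Beta(alpha, beta) with the given mean and variance:
#' `k = mean (1 - mean) / variance - 1`, `alpha = mean k`, `beta = (1 - mean) k`.
#'
#' @param mean Target mean, in (0, 1).
#' @param variance Target variance; must satisfy `0 < variance < mean (1 - mean)`.
#' @return A [beta_prior()].
#' @examples
#' moment_match_beta(0.5, 1 / 12)  # Beta(1, 1)
#' @export
moment_match_beta <- function(mean, variance) {
  stopifnot(length(mean) == 1L, length(variance) == 1L)
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("moment_match_beta: 'mean' must lie in (0, 1)", call. = FALSE)
  if (!is.finite(variance) || variance <= 0 || variance >= mean * (1 - mean))
    stop("moment_match_beta: need 0 < variance < mean*(1-mean); got variance = ",
         format(variance), call. = FALSE)
  k <- mean * (1 - mean) / variance - 1
  beta_prior(mean * k, (1 - mean) * k)
}

#' Beta prior from a penetrance point estimate and pseudo-observation count
#'
#' Parameterizes the prior as `alpha = mu * nu`, `beta = (1 - mu) * nu`, so its
#' variance is exactly `mu (1 - mu) / (1 + nu)`. `nu` is interpretable as the
#' number of hypothetical phenotyped heterozygotes the prior is worth.
#'
#' @param mu Prior mean penetrance, in (0, 1). Clamping out-of-range
#'   predictions is the caller's job.
#' @param nu Positive pseudo-observation count; `alpha + beta == nu`.
#' @return A [beta_prior()].
#' @examples
#' beta_from_mean_nu(0.3, 20)  # Beta(6, 14), variance 0.01
#' @export
beta_from_mean_nu <- function(mu, nu) {
  stopifnot(length(mu) == 1L, length(nu) == 1L)
  if (!is.finite(mu) || mu <= 0 || mu >= 1)
    stop("beta_from_mean_nu: 'mu' must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(nu) || nu <= 0)
    stop("beta_from_mean_nu: 'nu' must be > 0", call. = FALSE)
  beta_prior(mu * nu, (1 - mu) * nu)
}

#' Equal-tailed credible interval of a beta distribution
#'
#' @param alpha,beta Positive beta shapes (vectorized).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A two-column matrix with columns `low` and `high`.
#' @examples
#' credible_interval(1, 1)  # (0.025, 0.975)
#' @export
credible_interval <- function(alpha, beta, level = 0.95) {
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) || any(alpha <= 0) || any(beta <= 0))
    stop("credible_interval: shapes must be finite and > 0", call. = FALSE)
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("credible_interval: 'level' must lie in (0, 1)", call. = FALSE)
  tail <- (1 - level) / 2
  cbind(low = stats::qbeta(tail, alpha, beta),
        high = stats::qbeta(1 - tail, alpha, beta))
}

#' Conjugate posterior update of a beta prior with binomial counts
#'
#' Adds observed affected heterozygotes to `alpha` and unaffected to `beta`.
#' The posterior mean `(cases + alpha) / (cases + controls + alpha + beta)` is
#' the shrunken penetrance estimate: it lies between the prior mean and the
#' observed proportion whenever any heterozygote is observed.
#'
#' @param prior A [beta_prior()], or a list with per-variant numeric vectors
#'   `alpha` and `beta` (recycled against the counts).
#' @param cases Non-negative integer vector of affected heterozygotes.
#' @param controls Non-negative integer vector of unaffected heterozygotes.
#' @param level Credible level for the reported interval.
#' @return A data.frame with columns `alpha_post`, `beta_post`, `mean`,
#'   `variance`, `cri_low`, `cri_high`.
#' @examples
#' posterior_update(beta_prior(0.45, 2.73), cases = 20, controls = 0)
#' @export
posterior_update <- function(prior, cases, controls, level = 0.95) {
  if (any(!is.finite(cases)) || any(!is.finite(controls)) ||
      any(cases < 0) || any(controls < 0))
    stop("posterior_update: counts must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(prior$alpha)) || any(!is.finite(prior$beta)) ||
      any(prior$alpha <= 0) || any(prior$beta <= 0))
    stop("posterior_update: prior shapes must be > 0", call. = FALSE)
  a <- cases + prior$alpha
  b <- controls + prior$beta
  s <- a + b
  ci <- credible_interval(a, b, level)
  data.frame(alpha_post = a, beta_post = b,
             mean = a / s,
             variance = a * b / (s^2 * (s + 1)),
             cri_low = ci[, "low"], cri_high = ci[, "high"])
}

#' Empirical-Bayes beta prior pooled over a variant table
#'
#' Computes the weighted mean of the observed per-variant penetrances, with
#' weights from [heterozygote_weight()], estimates the variance as the mean
#' squared error between that mean and each observed penetrance, and
#' moment-matches the two into a beta prior shared by all variants.
#'
#' @param variants A validated variant table (see [load_dataset()]).
#' @param weighted_mse If `TRUE`, the MSE is also weighted by the heterozygote
#'   weights. Default `FALSE`: weights enter the mean only.
#' @return A [beta_prior()]. Fails if the penetrance spread is too small for a
#'   beta distribution with the pooled mean to exist (variance >= mean(1-mean)
#'   cannot occur; variance of 0 can, for constant observed penetrance).
#' @examples
#' cohort <- generate_cohort(sim_config(n_variants = 200, seed = 1))
#' empirical_prior(cohort$records)
#' @export
empirical_prior <- function(variants, weighted_mse = FALSE) {
  n <- total_heterozygotes(variants)
  if (length(n) < 2L) stop("empirical_prior: need >= 2 variants", call. = FALSE)
  p <- observed_penetrance(variants)
  w <- heterozygote_weight(n)
  m <- sum(w * p) / sum(w)
  v <- if (weighted_mse) sum(w * (p - m)^2) / sum(w) else mean((p - m)^2)
  if (v <= 0 || v >= m * (1 - m))
    stop("empirical_prior: degenerate penetrance spread (variance = ",
         format(v), ", mean = ", format(m),
         "); beta moment matching impossible", call. = FALSE)
  moment_match_beta(m, v)
}
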