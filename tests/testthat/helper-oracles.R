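# Independent numerical oracles. These deliberately avoid the package's own
# conjugate/closed-form code paths (and R's pbeta/qbeta where they are the
# thing under test).

# Posterior mean/variance by Simpson integration of
# binomial likelihood x beta prior over [0,1].
grid_posterior_oracle <- function(alpha0, beta0, cases, controls, n_pts = 1e5) {
  stopifnot(alpha0 >= 1, beta0 >= 1)  # keeps the integrand bounded
  if (n_pts %% 2 == 1) n_pts <- n_pts + 1
  p <- seq(0, 1, length.out = n_pts + 1)
  f <- p^(alpha0 - 1 + cases) * (1 - p)^(beta0 - 1 + controls)
  simpson <- function(y, h) h / 3 * (y[1] + y[length(y)] +
    4 * sum(y[seq(2, length(y) - 1, by = 2)]) +
    2 * sum(y[seq(3, length(y) - 2, by = 2)]))
  h <- 1 / n_pts
  z <- simpson(f, h)
  m1 <- simpson(f * p, h) / z
  m2 <- simpson(f * p^2, h) / z
  list(mean = m1, variance = m2 - m1^2)
}

# Beta CDF at q by trapezoid integration of the density, using the
# substitution t = x^alpha that removes the x = 0 endpoint singularity:
#   F(q) = (1 / (alpha B(alpha, beta))) \int_0^{q^alpha} (1 - t^{1/alpha})^{beta-1} dt
beta_cdf_oracle <- function(q, alpha, beta_, n_pts = 2e5) {
  t <- seq(0, q^alpha, length.out = n_pts + 1)
  y <- (1 - pmin(t^(1 / alpha), 1))^(beta_ - 1)
  h <- (q^alpha) / n_pts
  (sum(y) - (y[1] + y[length(y)]) / 2) * h / (alpha * beta(alpha, beta_))
}

# Weighted squared Pearson correlation by direct formula evaluation.
weighted_r2_oracle <- function(x, y, w) {
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  cov <- sum(w * (x - mx) * (y - my)) / sum(w)
  vx <- sum(w * (x - mx)^2) / sum(w)
  vy <- sum(w * (y - my)^2) / sum(w)
  cov^2 / (vx * vy)
}

# Quantile-and-clip oracle for regression weights (cap_weight mode).
cap_weights_oracle <- function(variances, q) {
  w <- 1 / variances
  cap <- as.numeric(stats::quantile(w, q))
  ifelse(w > cap, cap, w)
}
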