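test_that("heterozygote weights match the closed form and increase with n", {
  expect_equal(heterozygote_weight(1), 1 - 1 / 1.01, tolerance = 1e-12)
  expect_equal(heterozygote_weight(1), 0.009901, tolerance = 1e-4)
  expect_equal(heterozygote_weight(10), 0.900100, tolerance = 1e-6)
  w <- heterozygote_weight(1:500)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0.0099 & w < 1))
  expect_error(heterozygote_weight(0), "must be finite and >= 1")
})

test_that("moment matching recovers beta parameters and rejects impossible moments", {
  u <- moment_match_beta(0.5, 1 / 12)
  expect_equal(c(u$alpha, u$beta), c(1, 1), tolerance = 1e-12)
  # round trip from Beta(0.45, 2.73) moments
  a <- 0.45; b <- 2.73
  m <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  pr <- moment_match_beta(m, v)
  expect_equal(c(pr$alpha, pr$beta), c(a, b), tolerance = 1e-12)
  # property: random round trips to 1e-12
  set.seed(1)
  for (i in 1:25) {
    mm <- runif(1, 0.02, 0.98)
    vv <- runif(1, 1e-5, 0.99) * mm * (1 - mm)
    pr <- moment_match_beta(mm, vv)
    s <- pr$alpha + pr$beta
    expect_equal(pr$alpha / s, mm, tolerance = 1e-12)
    expect_equal(pr$alpha * pr$beta / (s^2 * (s + 1)), vv, tolerance = 1e-12)
  }
  expect_error(moment_match_beta(0.5, 0.25), "variance")
  expect_error(moment_match_beta(1.2, 0.01), "mean")
})

test_that("empirical prior matches hand arithmetic on the two-variant toy set", {
  v <- validate_variants(data.frame(
    variant_id = c("a", "b"), residue_index = 1:2, variant_class = "missense",
    n_affected = c(3L, 7L), n_unaffected_lit = c(7L, 3L), n_gnomad = 0L))
  # equal weights, m = 0.5, MSE = ((0.2)^2 + (0.2)^2)/2 = 0.04, k = 5.25
  pr <- empirical_prior(v)
  expect_equal(c(pr$alpha, pr$beta), c(2.625, 2.625), tolerance = 1e-12)
  # identical observed penetrances: zero variance is degenerate
  v$n_affected <- c(5L, 5L)
  v$n_unaffected_lit <- c(5L, 5L)
  expect_error(empirical_prior(validate_variants(v)), "degenerate")
})

test_that("posterior updates follow conjugate arithmetic and shrinkage", {
  pr <- beta_prior(0.45, 2.73)
  expect_equal(posterior_update(pr, 0, 0)$mean, 0.45 / 3.18, tolerance = 1e-12)
  expect_equal(posterior_update(pr, 20, 0)$mean, 20.45 / 23.18, tolerance = 1e-12)
  expect_equal(posterior_update(beta_prior(1, 1), 0, 0)$mean, 0.5)
  # posterior mean lies strictly between prior mean and observed proportion
  p0 <- mean(pr)
  post <- posterior_update(pr, 3, 7)
  expect_true(post$mean > p0 && post$mean < 0.3)
  # shrinkage distance grows with added cases (monotone pull away from the
  # prior mean once the posterior sits on one side of it)
  d <- sapply(0:30, function(k) abs(posterior_update(pr, k, 0)$mean - p0))
  expect_true(all(diff(d) >= 0))
  # conjugacy: sequential one-at-a-time updates equal the batch update
  a <- pr$alpha; b <- pr$beta
  for (i in 1:6) { a <- a + 1 }          # 6 cases
  for (i in 1:4) { b <- b + 1 }          # 4 controls
  batch <- posterior_update(pr, 6, 4)
  expect_equal(c(batch$alpha_post, batch$beta_post), c(a, b), tolerance = 1e-12)
  expect_error(posterior_update(pr, -1, 0), "counts")
})

test_that("posterior mean/variance agree with grid-integration Bayes to 1e-8", {
  set.seed(7)
  for (i in 1:50) {
    a0 <- runif(1, 1, 5); b0 <- runif(1, 1, 5)
    cases <- sample(0:10, 1); controls <- sample(0:10, 1)
    oracle <- grid_posterior_oracle(a0, b0, cases, controls)
    post <- posterior_update(beta_prior(a0, b0), cases, controls)
    expect_equal(post$mean, oracle$mean, tolerance = 1e-8)
    expect_equal(post$variance, oracle$variance, tolerance = 1e-8)
  }
})

test_that("credible intervals are equal-tailed and match the integration oracle", {
  expect_equal(credible_interval(1, 1)[1, ], c(low = 0.025, high = 0.975),
               tolerance = 1e-12)
  ci <- credible_interval(0.45, 2.73)
  expect_lt(abs(beta_cdf_oracle(ci[1, "low"], 0.45, 2.73) - 0.025), 1e-8)
  expect_lt(abs(beta_cdf_oracle(ci[1, "high"], 0.45, 2.73) - 0.975), 1e-8)
  # width strictly decreases as alpha+beta grows at fixed mean
  widths <- sapply(c(2, 5, 10, 50, 200), function(s) {
    ci <- credible_interval(0.3 * s, 0.7 * s)
    ci[1, "high"] - ci[1, "low"]
  })
  expect_true(all(diff(widths) < 0))
  expect_error(credible_interval(0, 1), "shapes")
})

test_that("mean/nu parameterization gives alpha+beta = nu and the stated variance", {
  pr <- beta_from_mean_nu(0.3, 20)
  expect_equal(c(pr$alpha, pr$beta), c(6, 14), tolerance = 1e-12)
  expect_equal(pr$alpha * pr$beta / ((pr$alpha + pr$beta)^2 * (pr$alpha + pr$beta + 1)),
               0.01, tolerance = 1e-12)
  pr2 <- beta_from_mean_nu(0.5, 19)
  expect_equal(0.25 / 20,
               pr2$alpha * pr2$beta / ((pr2$alpha + pr2$beta)^2 * (pr2$alpha + pr2$beta + 1)),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    mu <- runif(1, 0.01, 0.99); nu <- runif(1, 0.5, 200)
    pr <- beta_from_mean_nu(mu, nu)
    expect_equal(pr$alpha + pr$beta, nu, tolerance = 1e-12)
    expect_equal(pr$alpha * pr$beta / (nu^2 * (nu + 1)), mu * (1 - mu) / (1 + nu),
                 tolerance = 1e-12)
  }
  expect_error(beta_from_mean_nu(0, 10), "mu")
  expect_error(beta_from_mean_nu(0.5, -1), "nu")
})
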