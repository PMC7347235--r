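test_that("regression weights are capped inverse variances", {
  # equal variances: equal weights, cap inactive
  expect_equal(regression_weights(rep(0.02, 5)), rep(50, 5))
  # one tiny variance among many hits the cap
  v <- c(rep(0.1, 9), 1e-6)
  w <- regression_weights(v, 0.9)
  cap <- as.numeric(quantile(1 / v, 0.9))
  expect_equal(w[10], cap)
  # 10 known variances vs the quantile-and-clip oracle
  set.seed(4)
  v10 <- runif(10, 1e-4, 0.2)
  expect_equal(regression_weights(v10, 0.9), cap_weights_oracle(v10, 0.9),
               tolerance = 1e-12)
  expect_error(regression_weights(numeric(0)), "empty")
  expect_error(regression_weights(c(0.1, 0)), "finite")
})

test_that("pattern models recover an exact linear surface with zero noise", {
  v <- exact_linear_cohort()
  targets <- 0.1 + 0.3 * v$peak_current + 0.4 * v$penetrance_density
  models <- fit_pattern_models(v, targets, rep(1, nrow(v)))
  expect_length(models, 1L)
  m <- models[["11000000"]]
  expect_equal(unname(m$coefficients),
               c(0.1, 0.3, 0.4), tolerance = 1e-8)
  expect_equal(m$n_train, nrow(v))
  expect_lt(m$residual_variance, 1e-16)
})

test_that("each pattern trains on all records observing its features, not exact matches", {
  co <- generate_cohort(sim_config(n_variants = 600, seed = 21))
  v <- co$records
  keys <- pattern_of(v)
  obs <- !is.na(as.matrix(v[feature_names()]))
  models <- fit_pattern_models(v, observed_penetrance(v),
                               rep(1, nrow(v)))
  full_key <- paste(rep("1", 8), collapse = "")
  di_key <- "01111111"
  expect_true(all(c(full_key, di_key) %in% names(models)))
  m <- models[[full_key]]
  expect_equal(m$n_train, sum(rowSums(!obs) == 0))
  # density + in-silico pattern trains on the much larger superset
  superset <- sum(rowSums(!obs[, feature_names()[-1], drop = FALSE]) == 0)
  expect_equal(models[[di_key]]$n_train, superset)
  expect_gt(models[[di_key]]$n_train, m$n_train)
})

test_that("EM reaches a fixed point quickly on degenerate constant covariates", {
  n <- 40
  set.seed(8)
  v <- validate_variants(data.frame(
    variant_id = sprintf("c%02d", 1:n), residue_index = 1:n,
    variant_class = "missense",
    n_affected = rbinom(n, 200, 0.3), n_unaffected_lit = 0L, n_gnomad = 200L,
    peak_current = 0.7, penetrance_density = 0.4))
  v$n_gnomad <- 200L - v$n_affected  # total fixed at 200
  # contraction per iteration is nu/(nu + 200) < 0.1, so the fixed point is
  # reached within 3 iterations at the 1e-4 tolerance
  fit <- em_iterate(v, em_config(nu = 19))
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 3L)
  expect_equal(length(unique(round(fit$priors$mean, 12))), 1L)
})

test_that("EM results are deterministic, nu-parameterized, and traced", {
  co <- generate_cohort(sim_config(n_variants = 150, seed = 31))
  cfg <- em_config(nu = 19, max_iterations = 10)
  f1 <- suppressWarnings(em_iterate(co$records, cfg))
  f2 <- suppressWarnings(em_iterate(co$records, cfg))
  expect_identical(f1$priors, f2$priors)
  expect_identical(f1$posteriors, f2$posteriors)
  expect_identical(f1$trace, f2$trace)
  expect_equal(f1$priors$alpha_prior + f1$priors$beta_prior,
               rep(19, nrow(co$records)), tolerance = 1e-12)
  expect_true(all(f1$priors$mean > 0 & f1$priors$mean < 1))
  expect_equal(nrow(f1$trace), f1$n_iterations)
  # non-convergence is flagged loudly, trace still recorded
  expect_warning(f3 <- em_iterate(co$records, em_config(max_iterations = 2)),
                 "not converged")
  expect_false(f3$converged)
  expect_equal(nrow(f3$trace), 2L)
  # convergence flag matches the recorded trace in both directions
  expect_false(f1$converged)
  expect_gte(f1$trace$max_change[f1$n_iterations], cfg$convergence_tol)
  f4 <- em_iterate(co$records, em_config(nu = 19, max_iterations = 300))
  expect_true(f4$converged)
  expect_lt(f4$trace$max_change[f4$n_iterations], 1e-4)
})

test_that("with pure-noise features, EM prior means collapse toward the global mean", {
  cfg <- sim_config(n_variants = 400, seed = 13,
                    coefficients = c(intercept = 0.3, peak_current = 0,
                                     penetrance_density = 0),
                    noise_sd = 0.15)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(em_iterate(co$records,
                                     em_config(nu = 19, max_iterations = 100)))
  spread_obs <- sd(observed_penetrance(co$records))
  spread_prior <- sd(fit$priors$mean)
  expect_gt(spread_obs / spread_prior, 2)
})

test_that("predict_prior scores new feature vectors consistently", {
  v <- exact_linear_cohort()
  targets <- pmin(pmax(0.1 + 0.3 * v$peak_current + 0.4 * v$penetrance_density,
                       0), 1)
  models <- fit_pattern_models(v, targets, rep(1, nrow(v)))
  cfg <- em_config(nu = 19)
  # a training variant's own features reproduce its fitted value
  pr <- predict_prior(v[1, feature_names()], models, cfg)
  expect_equal(mean(pr), targets[1], tolerance = 1e-8)
  expect_equal(pr$alpha + pr$beta, 19, tolerance = 1e-12)
  # unseen pattern falls back to the largest usable feature subset or errors
  dens_only <- data.frame(penetrance_density = 0.5)
  expect_error(predict_prior(dens_only, models, cfg), "no fitted model")
  # all-missing features with a fallback return the fallback prior
  emp <- beta_prior(0.45, 2.73)
  out <- predict_prior(data.frame(sift = NA_real_), models, cfg,
                       fallback_prior = emp)
  expect_identical(out, emp)
})
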