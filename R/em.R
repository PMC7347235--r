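#' Configuration for the EM prior-imputation loop
#'
#' @param nu Pseudo-observation count the feature-imputed prior is worth
#'   (`alpha_prior + beta_prior == nu`). Default 19, the calibrated value for
#'   desk-scale cohorts; see [tune_nu()].
#' @param convergence_tol Absolute change in per-variant posterior mean
#'   penetrance below which the loop stops. Default 1e-4 (0.01 percentage
#'   points); `1e-2` gives the looser historical criterion.
#' @param max_iterations Hard iteration cap; non-convergence warns, never
#'   silently loops.
#' @param weight_cap_quantile Quantile at which the inverse-variance
#'   regression weights are capped ("ninth decile" = 0.9).
#' @param cap_mode `"cap_weight"` (default) caps the weight distribution at
#'   its `weight_cap_quantile` quantile; `"truncate_variance"` instead
#'   truncates the variance distribution at that quantile before inverting.
#' @param clamp_epsilon Regression predictions are clamped to
#'   `[clamp_epsilon, 1 - clamp_epsilon]` before the beta reparameterization,
#'   which needs an open-interval mean.
#' @param weighted_mse Passed to [empirical_prior()] for the initialization.
#' @param seed Integer seed recorded in results (the loop itself is
#'   deterministic; the seed matters for downstream simulation wrappers).
#' @return A list of class `em_config`.
#' @export
em_config <- function(nu = 19, convergence_tol = 1e-4, max_iterations = 50L,
                      weight_cap_quantile = 0.9,
                      cap_mode = c("cap_weight", "truncate_variance"),
                      clamp_epsilon = 1e-4, weighted_mse = FALSE, seed = 1L) {
  cap_mode <- match.arg(cap_mode)
  stopifnot(nu > 0, convergence_tol > 0, max_iterations >= 1,
            weight_cap_quantile > 0, weight_cap_quantile < 1,
            clamp_epsilon > 0, clamp_epsilon < 0.5)
  structure(list(nu = nu, convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 weight_cap_quantile = weight_cap_quantile,
                 cap_mode = cap_mode, clamp_epsilon = clamp_epsilon,
                 weighted_mse = weighted_mse, seed = as.integer(seed)),
            class = "em_config")
}

#' Capped inverse-variance regression weights
#'
#' Raw weights are the reciprocals of the posterior variances; to keep a
#' handful of very precisely estimated variants from dominating the
#' regression, weights are capped at the `cap_quantile` quantile of their own
#' distribution (default: the ninth decile).
#'
#' @param variances Positive posterior variances, one per variant.
#' @param cap_quantile Cap position in (0, 1); default 0.9.
#' @param mode See `cap_mode` in [em_config()].
#' @return Positive weights, same length as `variances`.
#' @export
regression_weights <- function(variances, cap_quantile = 0.9,
                               mode = c("cap_weight", "truncate_variance")) {
  mode <- match.arg(mode)
  if (length(variances) == 0L)
    stop("regression_weights: empty input", call. = FALSE)
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("regression_weights: variances must be finite and > 0", call. = FALSE)
  if (mode == "cap_weight") {
    w <- 1 / variances
    pmin(w, stats::quantile(w, cap_quantile, names = FALSE))
  } else {
    v <- pmin(variances, stats::quantile(variances, cap_quantile, names = FALSE))
    1 / v
  }
}

## Training rows for a feature subset: every variant with all of `feats` observed
## (a superset of the variants whose pattern is exactly `feats`).
pattern_training_rows <- function(obs, feats) {
  if (length(feats) == 0L) return(seq_len(nrow(obs)))
  which(rowSums(!obs[, feats, drop = FALSE]) == 0L)
}

#' Fit one weighted linear model per missingness pattern
#'
#' For each observed-feature pattern in the table, regresses the working
#' penetrance estimate on exactly the features that pattern observes, by
#' weighted least squares, training on *all* variants for which those
#' features are available (not only variants matching the pattern exactly).
#' A pattern whose training set is too small for its feature count falls back
#' by dropping its least-available feature until fittable; the terminal
#' fallback is an intercept-only model on the full table (the pooled mean).
#'
#' @param variants A validated variant table.
#' @param targets Per-variant penetrance estimates in \[0, 1\] (the working
#'   posterior means).
#' @param weights Positive per-variant weights (see [regression_weights()]).
#' @return Named list, one `pattern_model` per pattern key present, each with
#'   elements `pattern`, `features`, `coefficients` (intercept first),
#'   `n_train`, `residual_variance`, `aic`, `fallback_from` (`NA` unless the
#'   feature set was reduced).
#' @export
fit_pattern_models <- function(variants, targets, weights) {
  n <- nrow(variants)
  stopifnot(length(targets) == n, length(weights) == n)
  if (any(!is.finite(targets)) || any(targets < 0 | targets > 1))
    stop("fit_pattern_models: targets must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("fit_pattern_models: weights must be > 0", call. = FALSE)
  obs <- !is.na(as.matrix(variants[feature_names()]))
  keys <- pattern_of(variants)
  availability <- colSums(obs)
  models <- list()
  for (key in unique(keys)) {
    feats <- feature_names()[strsplit(key, "")[[1L]] == "1"]
    requested <- feats
    repeat {
      rows <- pattern_training_rows(obs, feats)
      if (length(rows) >= length(feats) + 2L) break
      feats <- feats[-which.min(availability[feats])]
    }
    dat <- data.frame(.y = targets[rows])
    for (f in feats) dat[[f]] <- variants[[f]][rows]
    fit <- stats::lm(.y ~ ., data = dat, weights = weights[rows])
    res <- stats::residuals(fit)
    wr <- weights[rows]
    coefs <- stats::coef(fit)
    coefs[is.na(coefs)] <- 0  # rank-deficient fits (e.g. constant feature)
    models[[key]] <- structure(list(
      pattern = key,
      features = feats,
      coefficients = coefs,
      n_train = length(rows),
      residual_variance = sum(wr * res^2) / sum(wr),
      aic = stats::AIC(fit),
      fallback_from = if (identical(feats, requested)) NA_character_ else
        pattern_key(feature_names() %in% requested)
    ), class = "pattern_model")
  }
  models
}

predict_pattern_model <- function(model, variants) {
  mu <- rep(model$coefficients[["(Intercept)"]], nrow(variants))
  for (f in model$features)
    mu <- mu + model$coefficients[[f]] * variants[[f]]
  mu
}

#' Iterative EM imputation of variant-specific beta priors
#'
#' Starting from the shared empirical-Bayes prior, alternates between
#' (E) computing per-variant posterior mean penetrances and inverse-variance
#' weights, and (M) refitting the pattern-mixture regression of those means on
#' the observed covariates. Each iteration converts the regression prediction
#' `mu_i` (clamped to an open interval) into the variant-specific prior
#' `Beta(mu_i nu, (1 - mu_i) nu)` and updates it with the variant's observed
#' affected/unaffected counts. The loop stops when no posterior mean moves by
#' more than `convergence_tol`.
#'
#' @param variants A validated variant table with >= 2 rows.
#' @param config An [em_config()].
#' @return An object of class `em_result`: `priors` and `posteriors`
#'   data.frames (one row per variant, with shapes, means, variances and 95%
#'   credible bounds), `models` (fitted pattern models of the final
#'   iteration), `trace` (per-iteration max/mean absolute change),
#'   `n_iterations`, `converged`, `empirical_prior`, `config`.
#' @export
em_iterate <- function(variants, config = em_config()) {
  stopifnot(inherits(config, "em_config"))
  variants <- validate_variants(variants)
  n <- nrow(variants)
  if (n < 2L) stop("em_iterate: need >= 2 variants", call. = FALSE)
  cases <- variants$n_affected
  controls <- variants$n_unaffected_lit + variants$n_gnomad

  emp <- empirical_prior(variants, weighted_mse = config$weighted_mse)
  post <- posterior_update(emp, cases, controls)
  prior_alpha <- rep(emp$alpha, n)
  prior_beta <- rep(emp$beta, n)
  models <- NULL
  trace <- data.frame(iteration = integer(), max_change = numeric(),
                      mean_change = numeric())
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    w <- regression_weights(post$variance, config$weight_cap_quantile,
                            config$cap_mode)
    models <- fit_pattern_models(variants, post$mean, w)
    keys <- pattern_of(variants)
    mu <- numeric(n)
    for (key in unique(keys)) {
      idx <- which(keys == key)
      mu[idx] <- predict_pattern_model(models[[key]], variants[idx, , drop = FALSE])
    }
    mu <- pmin(pmax(mu, config$clamp_epsilon), 1 - config$clamp_epsilon)
    prior_alpha <- mu * config$nu
    prior_beta <- (1 - mu) * config$nu
    new_post <- posterior_update(list(alpha = prior_alpha, beta = prior_beta),
                                 cases, controls)
    delta <- abs(new_post$mean - post$mean)
    trace <- rbind(trace, data.frame(iteration = iter, max_change = max(delta),
                                     mean_change = mean(delta)))
    post <- new_post
    if (max(delta) < config$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("em_iterate: not converged after ", iter, " iterations (last max change ",
            format(trace$max_change[iter]), ")", call. = FALSE)
  pci <- credible_interval(prior_alpha, prior_beta)
  priors <- data.frame(variant_id = variants$variant_id,
                       alpha_prior = prior_alpha, beta_prior = prior_beta,
                       mean = prior_alpha / (prior_alpha + prior_beta),
                       cri_low = pci[, "low"], cri_high = pci[, "high"])
  posteriors <- cbind(data.frame(variant_id = variants$variant_id), post)
  structure(list(priors = priors, posteriors = posteriors, models = models,
                 trace = trace, n_iterations = iter, converged = converged,
                 empirical_prior = emp, config = config),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("EM penetrance fit: %d variants, %d pattern model(s), %d iteration(s), %s\n",
              nrow(x$priors), length(x$models), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  nu = %g; empirical prior Beta(%.3g, %.3g)\n",
              x$config$nu, x$empirical_prior$alpha, x$empirical_prior$beta))
  invisible(x)
}

#' Feature-imputed prior for a (possibly never-observed) variant
#'
#' Scores a feature vector with the fitted pattern-mixture models: the model
#' matching the vector's own missingness pattern if present, otherwise the
#' fitted model using the largest subset of the observed features. The
#' clamped prediction becomes a `Beta(mu nu, (1 - mu) nu)` prior — available
#' before a single heterozygote of the variant has been phenotyped.
#'
#' @param features One-row data.frame (or named list) holding some or all of
#'   [feature_names()]; absent names count as missing.
#' @param models Fitted models from [fit_pattern_models()] or an
#'   `em_result$models`.
#' @param config The [em_config()] supplying `nu` and `clamp_epsilon`.
#' @param fallback_prior Optional [beta_prior()] returned when no feature is
#'   usable (e.g. the empirical prior). Without it, an unmatched pattern is an
#'   error listing the available patterns.
#' @return A [beta_prior()] with `alpha + beta == nu` (or `fallback_prior`).
#' @export
predict_prior <- function(features, models, config = em_config(),
                          fallback_prior = NULL) {
  row <- as.data.frame(as.list(features), stringsAsFactors = FALSE)
  for (f in setdiff(feature_names(), names(row))) row[[f]] <- NA_real_
  observed <- !is.na(unlist(row[feature_names()]))
  key <- pattern_key(observed)
  model <- models[[key]]
  if (is.null(model)) {
    usable <- Filter(function(m) all(m$features %in% feature_names()[observed]),
                     models)
    if (length(usable)) {
      sizes <- vapply(usable, function(m) length(m$features), integer(1))
      model <- usable[[which.max(sizes)]]
    }
  }
  if (is.null(model)) {
    if (!is.null(fallback_prior)) return(fallback_prior)
    stop("predict_prior: no fitted model applies to pattern ", key,
         "; available patterns: ", paste(names(models), collapse = ", "),
         call. = FALSE)
  }
  mu <- predict_pattern_model(model, row)
  mu <- pmin(pmax(mu, config$clamp_epsilon), 1 - config$clamp_epsilon)
  beta_from_mean_nu(mu, config$nu)
}
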