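#' Weighted coefficient of determination with bootstrap CI
#'
#' Squared weighted Pearson correlation between two series, with a seeded
#' percentile-bootstrap confidence interval over variants.
#'
#' @param predicted,target Numeric vectors of equal length >= 3.
#' @param weights Positive weights (default: equal, giving plain Pearson R2).
#' @param n_boot Bootstrap resamples for the CI (default 2000); 0 skips it.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return A list: `r2`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
weighted_r2 <- function(predicted, target, weights = NULL, n_boot = 2000L,
                        seed = 1L, level = 0.95) {
  n <- length(predicted)
  if (length(target) != n || n < 3L)
    stop("weighted_r2: need equal-length series of length >= 3", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("weighted_r2: weights must be positive, one per point", call. = FALSE)
  wcor2 <- function(x, y, w) {
    sw <- sum(w)
    mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    vx <- sum(w * (x - mx)^2) / sw; vy <- sum(w * (y - my)^2) / sw
    if (vx <= 0 || vy <= 0)
      stop("weighted_r2: zero variance in a series; R2 undefined", call. = FALSE)
    (sum(w * (x - mx) * (y - my)) / sw)^2 / (vx * vy)
  }
  r2 <- wcor2(predicted, target, weights)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(wcor2(predicted[idx], target[idx], weights[idx]),
               error = function(e) NA_real_)
    }, numeric(1))
    tail <- (1 - level) / 2
    ci <- stats::quantile(boots, c(tail, 1 - tail), na.rm = TRUE, names = FALSE)
  }
  list(r2 = r2, ci_low = ci[1L], ci_high = ci[2L], n = n, n_boot = n_boot)
}

#' Bland-Altman agreement summary
#'
#' Per-point averages and differences (`a - b`), the mean difference, and the
#' limits of agreement at mean difference +/- 1.96 standard deviations.
#'
#' @param series_a,series_b Numeric vectors of equal length >= 2.
#' @return A list of class `agreement_summary`: `points` data.frame
#'   (`average`, `difference`), `mean_difference`, `loa_low`, `loa_high`,
#'   `sd_difference`.
#' @export
bland_altman <- function(series_a, series_b) {
  n <- length(series_a)
  if (length(series_b) != n || n < 2L)
    stop("bland_altman: need equal-length series of length >= 2", call. = FALSE)
  d <- series_a - series_b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(points = data.frame(average = (series_a + series_b) / 2,
                                     difference = d),
                 mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$mean_difference, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' Sliding-window mean over variants ordered along the protein
#'
#' Orders values by residue index and smooths them with a centered moving
#' average over `window` neighboring variants (shrinking to the available
#' neighbors near the ends). Used to visualize how predicted penetrance
#' tracks protein topology.
#'
#' @param residue_index Positive integer positions, one per variant.
#' @param values Numeric values to smooth.
#' @param window Window size in variants (default 30).
#' @return A data.frame (`residue_index`, `value`, `smoothed`) sorted by
#'   residue (stable for ties).
#' @export
rolling_mean_by_residue <- function(residue_index, values, window = 30L) {
  n <- length(values)
  if (length(residue_index) != n)
    stop("rolling_mean_by_residue: lengths differ", call. = FALSE)
  if (window < 1L) stop("rolling_mean_by_residue: window must be >= 1", call. = FALSE)
  ord <- order(residue_index)
  v <- values[ord]
  left <- floor((window - 1) / 2)
  right <- window - 1L - left
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1L, i - left):min(n, i + right)]), numeric(1))
  data.frame(residue_index = residue_index[ord], value = v, smoothed = sm)
}

#' Default feature subsets for model comparison
#'
#' The standard comparison rows: functional assay alone, structural score
#' alone, the two combined, all eight features, and the sequence-based
#' in-silico scores alone.
#'
#' @return Named list of character vectors of feature names.
#' @export
default_feature_sets <- function() {
  list(peak_current = "peak_current",
       penetrance_density = "penetrance_density",
       peak_current_and_density = c("peak_current", "penetrance_density"),
       all_features = feature_names(),
       sequence_based = insilico_features())
}

#' Compare feature subsets by weighted R-squared and AIC
#'
#' For each feature subset, evaluates how well a prior built from only those
#' features predicts the posterior mean penetrance, under both prior schemes:
#' the "empirical" column regresses the shared-empirical-prior posterior
#' means on the subset (single weighted least-squares fit), and the "EM"
#' column re-runs the full EM with all other features masked out and scores
#' its imputed prior means against its posterior means. R-squared is weighted
#' by capped inverse posterior variance and computed on one common variant
#' subset (rows observing every feature used anywhere in the comparison), so
#' rows are comparable.
#'
#' @param variants A validated variant table.
#' @param feature_sets Named list of feature-name vectors
#'   (default [default_feature_sets()]).
#' @param config An [em_config()].
#' @param n_boot,seed Bootstrap parameters for the R-squared CIs.
#' @return A data.frame, one row per feature set: `feature_set`, `n_eval`,
#'   `r2_empirical`, `ci_low_empirical`, `ci_high_empirical`,
#'   `aic_empirical`, `r2_em`, `ci_low_em`, `ci_high_em`, `aic_em`.
#' @export
compare_feature_sets <- function(variants, feature_sets = default_feature_sets(),
                                 config = em_config(), n_boot = 2000L, seed = 1L) {
  variants <- validate_variants(variants)
  used <- unique(unlist(feature_sets))
  complete <- rowSums(is.na(as.matrix(variants[used]))) == 0L
  if (sum(complete) < 10L)
    stop("compare_feature_sets: fewer than 10 variants observe every feature used",
         call. = FALSE)
  eval_idx <- which(complete)
  cases <- variants$n_affected
  controls <- variants$n_unaffected_lit + variants$n_gnomad
  emp <- empirical_prior(variants, weighted_mse = config$weighted_mse)
  emp_post <- posterior_update(emp, cases, controls)
  emp_w <- regression_weights(emp_post$variance, config$weight_cap_quantile,
                              config$cap_mode)
  rows <- lapply(names(feature_sets), function(set_name) {
    feats <- feature_sets[[set_name]]
    # empirical column: one WLS fit of empirical posterior means on the subset
    dat <- data.frame(.y = emp_post$mean[eval_idx])
    for (f in feats) dat[[f]] <- variants[[f]][eval_idx]
    fit <- stats::lm(.y ~ ., data = dat, weights = emp_w[eval_idx])
    r2e <- weighted_r2(stats::fitted(fit), emp_post$mean[eval_idx],
                       emp_w[eval_idx], n_boot = n_boot, seed = seed)
    # EM column: full EM with other features masked out
    masked <- variants
    for (f in setdiff(feature_names(), feats)) masked[[f]] <- NA_real_
    em <- suppressWarnings(em_iterate(masked, config))
    em_w <- regression_weights(em$posteriors$variance,
                               config$weight_cap_quantile, config$cap_mode)
    r2m <- weighted_r2(em$priors$mean[eval_idx], em$posteriors$mean[eval_idx],
                       em_w[eval_idx], n_boot = n_boot, seed = seed)
    full_key <- pattern_key(feature_names() %in% feats)
    aic_em <- if (!is.null(em$models[[full_key]])) em$models[[full_key]]$aic else NA_real_
    data.frame(feature_set = set_name, n_eval = length(eval_idx),
               r2_empirical = r2e$r2, ci_low_empirical = r2e$ci_low,
               ci_high_empirical = r2e$ci_high, aic_empirical = stats::AIC(fit),
               r2_em = r2m$r2, ci_low_em = r2m$ci_low, ci_high_em = r2m$ci_high,
               aic_em = aic_em)
  })
  do.call(rbind, rows)
}
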