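## Synthetic cohort generator.
##
## Emulates the statistical shape of a literature-curated rare-variant
## cohort: a heavy-tailed heterozygote count distribution (most variants
## seen in one or two individuals, a few population-database variants with
## hundreds of carriers), true penetrance linearly linked to continuous
## covariates through a shared latent severity factor, binomial affected
## counts, and block missingness (functional assay rare, in-silico scores
## near-universal, structural score near-universal).

#' Simulation configuration for [generate_cohort()]
#'
#' Defaults state a cohort of the size and shape of a curated sodium-channel
#' variant table: 1,439 variants; functional data observed for ~16.5% of
#' variants (238/1439) and in-silico scores for ~96% (1382/1439); counts
#' heavy-tailed (~75% of variants drawn near 1-2 heterozygotes, the rest
#' log-normal with hundreds in the tail); true penetrance =
#' clamp(linear link + Gaussian noise) with slopes -0.35 on the functional
#' assay and +0.3 on the structural score, placed so the link stays inside
#' (0, 1) for essentially all variants (the linear model is then exactly
#' correct and recovery tests probe the estimator, not boundary mismatch).
#'
#' @param n_variants Number of variants (default 1439).
#' @param seed Integer seed.
#' @param coefficients Named numeric vector: `intercept` plus one slope per
#'   feature name (missing names mean slope 0).
#' @param noise_sd SD of Gaussian noise on the true-penetrance link (0.05).
#' @param tail_prob Probability a variant's count comes from the heavy tail.
#' @param tail_meanlog,tail_sdlog Log-normal parameters of the tail counts.
#' @param small_lambda Poisson rate of the small-count component (count =
#'   1 + Poisson(small_lambda)).
#' @param p_obs_functional,p_obs_density,p_obs_insilico Per-variant
#'   observation probabilities; in-silico scores are observed as a block.
#' @param p_indel Probability a variant is an in-frame indel (forces its
#'   in-silico scores missing).
#' @param p_gnomad Probability an unaffected heterozygote is a
#'   population-database carrier rather than a literature report.
#' @param penetrance_floor Lower clamp for true penetrance (background risk).
#' @param protein_length Residue indices are drawn from 1..protein_length.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 1439L, seed = 1L,
                       coefficients = c(intercept = 0.53, peak_current = -0.35,
                                        penetrance_density = 0.3,
                                        sift = 0.005, polyphen2 = 0.005,
                                        provean = 0.005, blast_pssm = 0.005,
                                        evolutionary_rate = 0.005, pam = 0.005),
                       noise_sd = 0.05,
                       tail_prob = 0.25, tail_meanlog = 2.3, tail_sdlog = 1.4,
                       small_lambda = 0.6,
                       p_obs_functional = 238 / 1439,
                       p_obs_density = 0.97,
                       p_obs_insilico = 1382 / 1439,
                       p_indel = 0.03, p_gnomad = 0.8,
                       penetrance_floor = 0.001,
                       protein_length = 2016L) {
  stopifnot(n_variants >= 1,
            all(c(p_obs_functional, p_obs_density, p_obs_insilico, p_indel,
                  p_gnomad, tail_prob) >= 0),
            all(c(p_obs_functional, p_obs_density, p_obs_insilico, p_indel,
                  p_gnomad, tail_prob) <= 1),
            noise_sd >= 0, penetrance_floor >= 0, penetrance_floor < 1)
  if (!"intercept" %in% names(coefficients))
    stop("sim_config: coefficients must include 'intercept'", call. = FALSE)
  extra <- setdiff(names(coefficients), c("intercept", feature_names()))
  if (length(extra))
    stop("sim_config: unknown coefficient name(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (p_obs_functional == 0 && p_obs_density == 0 && p_obs_insilico == 0)
    stop("sim_config: all features always missing; nothing to impute from",
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic variant cohort with known ground truth
#'
#' Draws correlated continuous features through a latent per-variant severity
#' factor, computes true penetrance from the configured linear link plus
#' noise (clamped to `[penetrance_floor, 1]`), draws total heterozygote
#' counts from the heavy-tailed mixture, draws affected counts binomially,
#' splits unaffected carriers between literature and population database,
#' and applies block missingness masks. Fully seeded and reproducible.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort`: `records` (a validated
#'   variant table), `true_penetrance`, `true_coefficients`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_variants
  z <- stats::rnorm(n)  # latent severity
  feats <- data.frame(
    peak_current = pmax(0, stats::rnorm(n, 1 - 0.2 * z, 0.1)),
    penetrance_density = pmax(0, stats::rnorm(n, 0.4 + 0.15 * z, 0.1)),
    sift = 0.4 * z + stats::rnorm(n, 0, sqrt(1 - 0.4^2)),
    polyphen2 = 0.4 * z + stats::rnorm(n, 0, sqrt(1 - 0.4^2)),
    provean = 0.4 * z + stats::rnorm(n, 0, sqrt(1 - 0.4^2)),
    blast_pssm = 0.3 * z + stats::rnorm(n, 0, sqrt(1 - 0.3^2)),
    evolutionary_rate = 0.3 * z + stats::rnorm(n, 0, sqrt(1 - 0.3^2)),
    pam = 0.3 * z + stats::rnorm(n, 0, sqrt(1 - 0.3^2)))
  co <- config$coefficients
  link <- rep(co[["intercept"]], n)
  for (f in feature_names())
    if (f %in% names(co)) link <- link + co[[f]] * feats[[f]]
  p_true <- pmin(pmax(link + stats::rnorm(n, 0, config$noise_sd),
                      config$penetrance_floor), 1)

  in_tail <- stats::runif(n) < config$tail_prob
  tot <- integer(n)
  tot[!in_tail] <- 1L + stats::rpois(sum(!in_tail), config$small_lambda)
  tot[in_tail] <- pmax(1L, as.integer(ceiling(
    stats::rlnorm(sum(in_tail), config$tail_meanlog, config$tail_sdlog))))
  affected <- stats::rbinom(n, tot, p_true)
  unaffected <- tot - affected
  gnomad <- stats::rbinom(n, unaffected, config$p_gnomad)

  is_indel <- stats::runif(n) < config$p_indel
  vclass <- ifelse(is_indel,
                   ifelse(stats::runif(n) < 0.5, "inframe_insertion",
                          "inframe_deletion"),
                   "missense")
  obs_fun <- stats::runif(n) < config$p_obs_functional
  obs_den <- stats::runif(n) < config$p_obs_density
  obs_ins <- (stats::runif(n) < config$p_obs_insilico) & !is_indel
  feats$peak_current[!obs_fun] <- NA_real_
  feats$penetrance_density[!obs_den] <- NA_real_
  for (f in insilico_features()) feats[[f]][!obs_ins] <- NA_real_

  residue <- sample.int(config$protein_length, n, replace = TRUE)
  records <- data.frame(
    variant_id = sprintf("var_%05d", seq_len(n)),
    protein_change = sprintf("p.Res%d", residue),
    residue_index = residue,
    variant_class = vclass,
    n_affected = affected,
    n_unaffected_lit = unaffected - gnomad,
    n_gnomad = gnomad)
  records <- cbind(records, feats)
  records <- validate_variants(records)
  structure(list(records = records, true_penetrance = p_true,
                 true_coefficients = co, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tot <- total_heterozygotes(x$records)
  cat(sprintf(paste0("Synthetic cohort: %d variants (seed %d); heterozygotes ",
                     "median %d, max %d; mean true penetrance %.3f\n"),
              nrow(x$records), x$config$seed, stats::median(tot), max(tot),
              mean(x$true_penetrance)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the dataset CSV in the canonical dialect (round-trips through
#' [load_dataset()]) and a companion truth CSV (`variant_id`,
#' `true_penetrance`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector with paths `dataset` and `truth`.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- file.path(dir, "dataset.csv")
  truth <- file.path(dir, "truth.csv")
  write_dataset(cohort$records, dataset)
  utils::write.csv(data.frame(variant_id = cohort$records$variant_id,
                              true_penetrance = cohort$true_penetrance),
                   truth, row.names = FALSE)
  c(dataset = dataset, truth = truth)
}
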