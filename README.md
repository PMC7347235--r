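# varpenet

Variant-specific disease penetrance estimation with beta-binomial empirical
Bayes and pattern-mixture EM priors.

## What it is for

Clinical geneticists interpreting rare coding variants in a
well-established disease gene (the motivating case: loss-of-function
variants in the cardiac sodium channel and Brugada syndrome) need the
probability that a carrier of a *specific* variant will develop disease —
its penetrance — together with honest uncertainty. Most variants are seen
in one or two people, so the raw fraction affected/total is useless on its
own. `varpenet` produces per-variant posterior penetrance estimates with
95% credible intervals by combining:

1. **Conjugate beta-binomial shrinkage.** With affected count $a$,
   unaffected count $b$ (population-database carriers counted unaffected)
   and prior $\mathrm{Beta}(\alpha_0,\beta_0)$, the posterior mean
   penetrance is
   $\hat p = (a + \alpha_0)\,/\,(a + b + \alpha_0 + \beta_0)$.
2. **An empirical-Bayes prior** moment-matched to the weighted mean
   (weights $w = 1 - 1/(0.01+n)$, $n$ = heterozygotes per variant) and MSE
   variance of the observed proportions.
3. **Feature-imputed variant-specific priors**: an iterative EM
   pattern-mixture regression of penetrance on peak channel current,
   structural penetrance density, and in-silico conservation scores — one
   weighted model per missingness pattern, so nothing is imputed — with
   the prediction $\mu$ converted to a prior
   $\mathrm{Beta}(\mu\nu, (1-\mu)\nu)$ worth $\nu$ hypothetical
   phenotyped heterozygotes.

Supporting tooling: credible-interval coverage simulation for calibrating
$\nu$ (`coverage_rate()`, `tune_nu()`), a carrier-misclassification
sensitivity experiment (`misclassify_experiment()`), model-comparison and
agreement diagnostics (`weighted_r2()`, `bland_altman()`,
`rolling_mean_by_residue()`, `compare_feature_sets()`), a fully seeded
synthetic-cohort generator with known ground truth (`generate_cohort()`),
and a CLI (`run_cli()`, wrapper in `inst/scripts/varpenet`).

See `vignettes/penetrance-model.Rmd` for the model, assumptions, and
numerical choices.

## Worked example

```r
library(varpenet)

co  <- generate_cohort(sim_config(n_variants = 400, seed = 7))
co
#> Synthetic cohort: 400 variants (seed 7); heterozygotes median 2, max 275; mean true penetrance 0.303

empirical_prior(co$records)
#> Beta prior: alpha = 0.1405, beta = 0.3323 (mean 0.2973, worth 0.4728 heterozygotes)

fit <- em_iterate(co$records, em_config(nu = 19, max_iterations = 300))
fit
#> EM penetrance fit: 400 variants, 7 pattern model(s), 71 iteration(s), converged
#>   nu = 19; empirical prior Beta(0.141, 0.332)

head(fit$posteriors[, c("variant_id", "mean", "cri_low", "cri_high")], 3)
#>   variant_id      mean    cri_low  cri_high
#> 1  var_00001 0.5476719 0.41849309 0.6736799
#> 2  var_00002 0.1265772 0.02459185 0.2945192
#> 3  var_00003 0.1280993 0.02384360 0.3012609

bland_altman(fit$priors$mean, fit$posteriors$mean)
#> Bland-Altman: mean difference -7.157e-05, limits of agreement [-0.071, 0.07086] (n = 400)
```

Reading the output: the pooled empirical prior is worth under half a
hypothetical heterozygote — the cohort-wide penetrance spread is huge, so
pooling alone says little about any one variant. After EM imputation each
variant's prior is worth ν = 19 heterozygotes of feature information;
variant `var_00001` (many carriers, strong functional signal in this
simulation) gets a posterior mean penetrance of 0.55 with a 0.42–0.67
credible interval, while `var_00002` is pulled near the benign range. The
Bland-Altman mean difference of −7×10⁻⁵ between prior and posterior means
shows the feature-imputed priors are not systematically biased against the
count data.

For real data, load a per-variant CSV (counts + covariates, empty cell =
missing) with `load_dataset()`; the column mapping is configurable via
`default_dialect()`.

## Command line

```sh
Rscript inst/scripts/varpenet simulate --n-variants 400 --seed 7 --out-dir sim/
Rscript inst/scripts/varpenet fit-em --input sim/dataset.csv --nu 19 \
    --max-iter 300 --out-dir fit/
Rscript inst/scripts/varpenet sensitivity --input sim/dataset.csv \
    --flips 24 --reps 200 --seed 1 --out-dir sens/
```

Every run writes a `manifest.json` sufficient to replay it bit-identically.

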