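# epiage

Comparative epigenetic-aging analysis for methylation beta matrices.

When two cohorts of the same genotype live in different environments —
say, mice kept in a standard laboratory colony versus animals released
into an outdoor field enclosure — their epigenomes may age at different
speeds. `epiage` quantifies this from probes-by-samples beta matrices
(methylation fractions in [0, 1]) with known sample ages:

* **Per-CpG aging rates.** For each probe and environment, OLS of beta on
  `[1, age_years, male]`; the age slope `b` (fraction/year) is the
  epigenetic aging rate, with exact t-tests and Benjamini–Hochberg
  q-values across probes. A pooled model
  `beta ~ age + env + age:env (+ sex)` tests the age-by-environment
  interaction per site.
* **Rate comparison.** Sites are categorized by joint significance and
  slope signs (q < 0.01 by default); (lab, field) slope pairs are
  summarized over eight 45° angular octants; the cohort rate ratio is
  estimated by zero-intercept regression of field on lab rates,
  `r = Σxy / Σx²` with a 95% CI, so `(r − 1)·100` is "% faster in the
  field"; Spearman concordance and counts of interaction-significant
  sites aging faster afield complete the picture.
* **Probe-set enrichment.** One-sided Fisher exact (hypergeometric tail)
  tests of query CpG sets — built from q, direction and effect-size
  filters — against a background probe universe, with GMT input.
* **Epigenetic clocks.** Elastic-net age predictors (months) over
  autosomal probes with MAE-minimizing cross-validation; cohort
  comparison of prediction residuals (age acceleration) by Wilcoxon
  rank-sum.
* **Synthetic truth.** A two-cohort methylome generator with exact
  per-site ground truth (site classes that gain or lose methylation,
  environment rate multipliers, sex-linked sites on X/Y, missingness)
  drives parameter-recovery tests for every stage.

The package is written Bioconductor-style: the central container
`BetaSet` extends `SummarizedExperiment` (beta assay + sample sheet +
probe annotation), and results come back as S4 objects or `DataFrame`s
with accessors.

## Worked example

```r
library(epiage)

sim <- simulateCohorts(SimConfig(nProbes = 5000, seed = 7))
sim$betas
#> BetaSet with 5000 probes and 61 samples
#>   environments: field=41, lab=20
#>   ages: 28.4948-222.146 days
#>   missing beta calls: 3.04%

lab   <- fitAgeModel(sim$betas, "lab")
field <- fitAgeModel(sim$betas, "field")
cats  <- categorizeSites(lab, field, qThresh = 0.01)
table(cats$category)
#>       joint_hyper        joint_hypo field_up_lab_down field_down_lab_up
#>                56                38                 0                 0
#>      lab_only_sig    field_only_sig   not_significant
#>                 0               255              4651

zeroInterceptRatio(cats$slope_lab, cats$slope_field,
                   cats$category == "joint_hyper")
#> RateRatio: 1.763 (95% CI 1.677-1.849, normal), n = 56 sites
#>   field rates 76.3% faster than lab

inter <- fitInteractionModel(sim$betas)
countInteractionDirections(cats, inter)
#>      category n_faster_field n_total percent
#> 1 joint_hyper             34      34     100
#> 2  joint_hypo              0       0      NA
```

Reading this: of 5000 simulated sites, 349 are age-associated (q < 0.01
in at least one cohort). Among the 56 jointly hypermethylating sites the
field cohort's rates are estimated 76% faster than the lab's (the
generative multiplier was 1.94; the gap is errors-in-variables
attenuation from lab-slope noise — see the methods vignette), and every
one of the 34 sites with a significant age-by-environment interaction
ages faster in the field. `trainClock` / `predictAge` /
`compareResiduals` then quantify the same acceleration as a clock
residual gap, and `runPipeline(runConfig(...))` drives all stages end to
end, writing one TSV per stage plus a run manifest. A subcommand CLI
over the same functions lives at `inst/scripts/epiage-cli.R`
(`simulate`, `fit`, `fit-interaction`, `compare`, `enrich`, `clock`,
`run`).

See the methods vignette
(`vignettes/comparative-epigenetic-aging.Rmd`) for the models,
assumptions, generator design and numerical conventions.

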