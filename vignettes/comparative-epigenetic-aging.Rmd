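---
title: "Comparing epigenetic aging rates between environments with epiage"
author: "epiage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing epigenetic aging rates between environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiage)
```

# The scientific problem

DNA methylation at individual CpG sites drifts with age: some sites gain
methylation (typically lowly methylated promoter/Polycomb sites), others
lose it. The per-site *epigenetic aging rate* is the slope of the
methylation fraction (beta value) regressed on chronological age, in
fraction per year. When two genetically identical cohorts live in
different environments — for instance inbred mice kept in a standard
laboratory colony versus littermate-equivalent animals released into an
outdoor field enclosure — comparing these per-site rates asks whether the
environment changes how fast the epigenome ages, and where.

`epiage` implements that comparison as a pipeline over a probes-by-samples
beta matrix:

1. **Site-wise models** (`fitAgeModel`): per probe and per environment,
   OLS of beta on `[1, age_years, male]` with exact t-tests on the age
   slope and BH q-values across probes.
2. **Interaction model** (`fitInteractionModel`): per probe, the pooled
   model `beta ~ age + environment + age:environment (+ sex)`; the
   interaction coefficient is the field-minus-lab rate difference.
3. **Rate comparison** (`categorizeSites`, `octantSummary`,
   `zeroInterceptRatio`, `rateConcordance`,
   `countInteractionDirections`): classification of slope pairs by joint
   significance, eight 45° angular octants of the (lab, field) rate
   plane, a zero-intercept regression of field on lab rates whose
   coefficient is the cohort rate ratio, Spearman concordance, and counts
   of interaction-significant sites aging faster afield.
4. **Probe-set enrichment** (`selectQuery`, `testEnrichment`): one-sided
   Fisher exact (hypergeometric tail) tests of query CpG sets against a
   background probe universe, e.g. transcription-factor binding probe
   sets in GMT format.
5. **Epigenetic clock** (`trainClock`, `predictAge`,
   `compareResiduals`): an elastic-net age predictor over autosomal
   probes, with cohort comparison of prediction residuals
   (predicted − chronological age, months) as a one-number readout of
   age acceleration.

All of it is exercised against a synthetic two-cohort methylome generator
(`simulateCohorts`) with known per-site truth, so every stage has a
parameter-recovery test that needs no external data.

# The models and their assumptions

## Site-wise aging rates

For probe $i$ in environment $e$ the model is

$$\beta_{ij} = \mu_i + b_{i,e}\,t_j + s_i\,\mathrm{male}_j + \varepsilon_{ij},$$

with $t_j$ the age of sample $j$ in years (days / 365.25) and
$b_{i,e}$ the epigenetic aging rate. Fits are per-probe complete-case
OLS; probes are grouped by missingness pattern so the all-observed
majority is solved in one matrix operation, and inference is the exact
t-test with $n_\text{used} - k$ degrees of freedom. Assumptions are the
usual ones for per-site linear EWAS models: linear drift over the
sampled age range, homoskedastic Gaussian residuals on the beta scale,
independent samples (no litter/relatedness structure).

Two degenerate-fit conventions keep noiseless fixtures well-defined: a
model that interpolates its data exactly yields $p = 0$ for a nonzero
coefficient and $p = 1$ for a zero one.

The interaction model pools both cohorts,

$$\beta_{ij} = \mu_i + b_i\,t_j + c_i\,F_j + d_i\,t_j F_j
  + s_i\,\mathrm{male}_j + \varepsilon_{ij},$$

with $F_j$ the field indicator; $d_i$ is the rate difference and is
tested per probe with BH adjustment. Whether sex belongs in the
interaction model is genuinely open (the per-environment fits adjust for
it, so we include it by default); `includeSex = FALSE` drops it.

## Rate comparison

Sites are categorized at a strict threshold (default $q < 0.01$) in
each environment; the "age-associated" analysis set is everything
significant in at least one environment, and that set is also the
default mask for the octant summary — the natural reading of
percentages reported over sites "with age-associated methylation
change", though the mask is configurable.

Octants are half-open 45° sectors counterclockwise from the positive
lab axis, so a pair exactly on a boundary (e.g. equal rates, 45°)
belongs to the upper sector, and (0, 0) pairs are excluded; both choices
make counts deterministic.

The cohort rate ratio is the coefficient of the no-intercept regression
of field rates on lab rates over a jointly significant set:
$\hat r = \sum x_i y_i / \sum x_i^2$. Its 95% CI uses the classical
no-intercept OLS standard error with $n - 1$ degrees of freedom; a
site-resampling bootstrap is available (`ciMethod = "bootstrap"`).
**Limitation:** the classical CI is conditional on fixed $x$. In
practice both axes are *estimated* rates, and measurement error in the
lab rates attenuates the ratio toward 1 (classical errors-in-variables),
increasingly so as lab cohorts shrink or noise grows. The coverage
simulation in the test suite therefore regresses estimated field rates
on the generator's *true* lab rates — the design under which the 95%
claim is well-defined — and the attenuation on fully estimated data is
visible in the package's own synthetic end-to-end runs, where recovered
ratios sit a few percent below the generative multipliers.

"Faster in the field" is an absolute-rate statement: at jointly
hypermethylating sites it means a positive interaction coefficient, at
jointly hypomethylating sites a negative one (more negative slope).

## Enrichment

Queries are built from a fit by three filters: $q$ below a threshold
(default 0.05), slope sign matching the requested direction, and effect
magnitude at least `effectThresh` (default 0.15), where effect =
slope/year × `referenceDuration` (default 1 year). The effect scale of
published thresholds is rarely stated, so the reference duration is
exposed rather than hard-coded; reproducing a specific query size may
require calibrating it. Each probe set is intersected with the declared
universe and tested with the one-sided Fisher exact p — computed as the
hypergeometric upper tail $P(X \ge \text{overlap})$ — plus the log2
odds ratio of the 2×2 table, with BH across the collection. Sets
disjoint from the universe yield $n_\text{set} = 0$, $p = 1$.

## The clock

`trainClock` fits an elastic net (via glmnet) of age in months
(days / 30.44) on beta values, restricted to autosomal probes —
sex-chromosome probes are excluded *before* fitting, so they can never
be features. Defaults follow standard practice for methylation clocks:
mixing `alpha = 0.5` and the penalty chosen on a lambda path by 10-fold
cross-validation minimizing mean absolute error, folds drawn from a
fixed seed. Features are standardized internally and coefficients
returned on the beta scale (this affects which probes are selected at a
fixed lambda, hence it is stated). Training means of the selected
features are stored and used to impute missing betas at prediction time;
samples with more than 20% of features imputed are flagged. Externally
published clocks are imported as flat coefficient tables
(`readClockModel`), never re-derived.

Residuals (predicted − chronological age) are compared between cohorts
with a two-sided Wilcoxon rank-sum test by default — consistent with
median-based reporting of residuals — with a Welch t-test behind
`test = "t"`.

# The synthetic generator

`SimConfig()` defaults are the study conditions this pipeline is built
around: 20 laboratory and 41 field samples aged 26–225 days, and
field/lab rate multipliers 1.94 at hypermethylating and 1.28 at
hypomethylating sites (i.e. field rates 94% and 28% faster). Values the
underlying data do not pin down were fixed once at realistic levels and
are documented here:

| parameter | default | rationale |
|---|---|---|
| `nProbes` | 20 000 | desk-scale stand-in for a ~275 K-site array; large enough for stable octant/ratio summaries |
| `classFractions` | hyper 0.06, hypo 0.04, null 0.89, sex_linked 0.01 | puts the age-associated share near the ~11% seen on real arrays at these cohort sizes |
| `slopeScalePerYear` | 0.1 | half-normal dispersion of lab rates; at the default cohort sizes this yields a realistic minority of sites reaching q < 0.01 (a 0.05 dispersion leaves essentially none, since the 20-sample lab slope SE is ≈0.03/year) |
| `noiseSd` | 0.02 | typical beta-scale residual noise for array data |
| `sexEffect` | 0.15 | comfortably detectable male–female offset at sex-linked sites |
| `missingRate` | 0.03 | mirrors the few-percent site loss of missing-value filtering |

Probe classes are assigned in deterministic index blocks (class counts
are exact, not multinomial); ages are uniform over the range and sexes
alternate within cohort (balanced design); baselines are uniform on
[0.2, 0.8], restricted to [0.2, 0.5] at hyper and [0.5, 0.8] at hypo
sites so trajectories stay clear of the [0, 1] clamp — which also
matches the biology of gaining sites starting low and losing sites
starting high. Noise is Gaussian on the beta scale with clamping;
logit-normal noise, probe-level chemistry (design type, detection
p-values), litter structure and nonlinear trajectories are deliberately
out of scope. Consequently, passing recovery tests demonstrate the
statistical machinery, not robustness to heteroskedastic or bounded-
support noise near the beta extremes, batch structure, or related
samples — all absent from the generator.

# Numerical choices

* Age units: days in, years for rates (÷365.25), months for the clock
  (÷30.44). Unit equivariance is tested.
* Sample order: fits internally sort samples by id, making results
  bit-identical under input permutation.
* Missingness: per-probe complete cases; probes with missing fraction
  above `maxMissing` (default 0.2) or fewer complete cases than model
  columns + 1 carry `NA` statistics and are excluded from BH.
  The exact filtering rule behind published "~275 K of ~285 K sites"
  counts is typically unstated; the max-missing-fraction filter is our
  explicit, configurable stand-in.
* Multiple testing: BH throughout (`stats::p.adjust`); the q-value
  method behind published tables is usually an upstream-tool default,
  and BH is that default in the array ecosystem.
* Zero residual variance: p = 0 (nonzero coefficient) or 1 (zero), as
  above; rank-deficient designs (e.g. a single-sex complete-case
  subset) return `NA` for the inestimable coefficient rather than
  failing.
* Octant boundaries: half-open, counterclockwise; origin excluded.
* Reproducibility: one seed per run; the pipeline derives fixed
  per-stage substreams from it, so stages are reproducible in
  isolation.

# Problem sizes used in tests

The bundled checks run at desk scale, chosen as the smallest sizes at
which each property is statistically sharp: oracle-equivalence fits at
100 probes × 40 samples; interaction calibration on all-null simulations
of 2000 probes × 60 samples; rate-ratio CI coverage over 200 replicates
per multiplier {1.25, 1.5, 2} with 2000 informative sites; the clock
direction property over 100 replicates of 300-probe, 30+30-sample
cohorts; the end-to-end synthetic analysis at 20 000 probes with the
default 20+41 design.

# Known limitations

Beyond the generator simplifications above: the rate-ratio point
estimate on fully estimated slopes carries errors-in-variables
attenuation (quantified honestly by the package's own synthetic runs);
site selection at strict thresholds induces winner's-curse inflation of
|slope| estimates that the package does not shrink (empirical-Bayes
shrinkage is out of scope); and the clock's cross-validated penalty on
small training sets is variable fold-to-fold, which is why the fold seed
is part of the model metadata.
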