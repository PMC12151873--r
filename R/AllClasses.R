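#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# days -> years / months conversions used throughout; rates are per-year,
# clock ages are in months.
DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44

SEX_LEVELS <- c("F", "M")
ENV_LEVELS <- c("lab", "field")
SEX_CHROMS <- c("X", "Y", "chrX", "chrY")
NONAUTOSOMES <- c(SEX_CHROMS, "MT", "chrM", "chrMT", "M")
PROBE_CLASSES <- c("cg", "ch", "rs")

SITE_CATEGORIES <- c("joint_hyper", "joint_hypo", "field_up_lab_down",
                     "field_down_lab_up", "lab_only_sig", "field_only_sig",
                     "not_significant")

#' Container for a methylation beta matrix with sample and probe metadata
#'
#' `BetaSet` extends \linkS4class{SummarizedExperiment} with a single
#' `"beta"` assay holding methylation fractions (probes as rows, samples as
#' columns, `NA` for missing calls).  Column data must carry `age_days`,
#' `sex` (`"F"`/`"M"`) and `environment` (`"lab"`/`"field"`); an optional
#' `exposure_group` column records finer cohort structure.  Row data may
#' carry `chrom` and `probe_class` (cg/ch/rs) annotation used for
#' autosome-restricted steps such as clock training.
#'
#' @aliases BetaSet-class
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- character()
    if (!("beta" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (!is.numeric(b))
            msg <- c(msg, "beta values must be numeric")
        else {
            rng <- range(b, na.rm = TRUE)
            if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
                msg <- c(msg, "beta values must lie in [0, 1]")
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    for (f in c("age_days", "sex", "environment"))
        if (!(f %in% colnames(cd)))
            msg <- c(msg, sprintf("colData column '%s' is required", f))
    if ("age_days" %in% colnames(cd) && any(cd$age_days <= 0, na.rm = TRUE))
        msg <- c(msg, "ages must be positive (days)")
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% SEX_LEVELS))
        msg <- c(msg, "sex must be 'F' or 'M'")
    if ("environment" %in% colnames(cd) && !all(cd$environment %in% ENV_LEVELS))
        msg <- c(msg, "environment must be 'lab' or 'field'")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic two-cohort methylome generator
#'
#' Holds the ground-truth parameters of the simulated aging methylome:
#' cohort sizes, age range in days, the mix of probe classes
#' (`hyper`/`hypo`/`null`/`sex_linked`), the dispersion of baseline (lab)
#' aging rates, the field/lab rate multipliers for hyper- and
#' hypomethylating sites, the sex offset at sex-linked probes, the beta-scale
#' noise standard deviation, the missing-call rate, and the seed.  Defaults
#' mirror the rewilding study design: 20 laboratory and 41 field livers aged
#' 26-225 days, with field rates 94% (hyper) and 28% (hypo) faster than lab.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nProbes = "integer",
    nLab = "integer",
    nField = "integer",
    ageRangeDays = "numeric",
    classFractions = "numeric",
    slopeScalePerYear = "numeric",
    rateRatioHyper = "numeric",
    rateRatioHypo = "numeric",
    sexEffect = "numeric",
    noiseSd = "numeric",
    missingRate = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nProbes < 1L || object@nLab < 1L || object@nField < 1L)
        msg <- c(msg, "probe and sample counts must be positive")
    ar <- object@ageRangeDays
    if (length(ar) != 2L || any(ar <= 0) || ar[1] >= ar[2])
        msg <- c(msg, "ageRangeDays must be (min, max) with 0 < min < max")
    cf <- object@classFractions
    if (!identical(sort(names(cf)), sort(c("hyper", "hypo", "null", "sex_linked"))))
        msg <- c(msg, "classFractions must be named hyper/hypo/null/sex_linked")
    else if (any(cf < 0) || abs(sum(cf) - 1) > 1e-8)
        msg <- c(msg, "classFractions must be nonnegative and sum to 1")
    if (object@slopeScalePerYear < 0 || object@rateRatioHyper < 0 ||
        object@rateRatioHypo < 0 || object@noiseSd < 0)
        msg <- c(msg, "rates and scales must be nonnegative")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Per-probe age-model fit for one environment
#'
#' One row per probe of the input matrix: complete-case count `n_used`, the
#' epigenetic aging rate `slope_per_year` (methylation fraction per year of
#' chronological age) with its standard error and two-sided t-test
#' p/q-values, and the male-vs-female methylation offset `sex_coef` with its
#' p/q.  Probes failing the missingness filter or with fewer than four
#' complete cases carry `NA` statistics and are excluded from the BH
#' adjustment.
#'
#' @aliases SiteWiseFit-class
#' @exportClass SiteWiseFit
setClass("SiteWiseFit", representation(
    results = "DFrame",
    modelEnvironment = "character",
    nSamples = "integer",
    maxMissing = "numeric"
))

#' Per-probe age-by-environment interaction fit
#'
#' One row per probe of the joint two-cohort model
#' `beta ~ age + environment + age:environment (+ sex)`: the lab-reference
#' age slope `age_coef`, the field-minus-lab slope difference
#' `age_env_coef` with standard error, and its two-sided p/q-values.
#'
#' @aliases InteractionFit-class
#' @exportClass InteractionFit
setClass("InteractionFit", representation(
    results = "DFrame",
    nSamples = "integer",
    maxMissing = "numeric",
    sexAdjusted = "logical"
))

#' Zero-intercept cohort rate ratio
#'
#' The slope of field aging rates regressed on lab aging rates through the
#' origin: `ratio` with a 95% confidence interval, the derived percentage
#' `pctFaster = (ratio - 1) * 100`, and the number of sites used.
#'
#' @aliases RateRatio-class
#' @exportClass RateRatio
setClass("RateRatio", representation(
    ratio = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    nSites = "integer",
    ciMethod = "character"
))

setValidity("RateRatio", function(object) {
    msg <- character()
    if (object@nSites < 2L)
        msg <- c(msg, "a rate ratio requires at least 2 sites")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        !(object@ciLow <= object@ratio && object@ratio <= object@ciHigh))
        msg <- c(msg, "confidence interval must bracket the ratio")
    if (length(msg)) msg else TRUE
})

#' Sparse elastic-net epigenetic clock
#'
#' A linear age predictor over autosomal probes: feature probe ids with
#' nonzero weights (methylation fraction to months of age), an intercept in
#' months, per-feature training means used to impute missing betas at
#' prediction time, and training metadata (alpha, lambda, fold count, seed,
#' training size).
#'
#' @aliases ClockModel-class
#' @exportClass ClockModel
setClass("ClockModel", representation(
    probes = "character",
    weights = "numeric",
    intercept = "numeric",
    featureMeans = "numeric",
    alpha = "numeric",
    lambda = "numeric",
    nFolds = "integer",
    seed = "integer",
    nTrain = "integer"
))

setValidity("ClockModel", function(object) {
    msg <- character()
    if (length(object@probes) != length(object@weights))
        msg <- c(msg, "one weight per feature probe is required")
    if (length(object@featureMeans) != length(object@probes))
        msg <- c(msg, "one training mean per feature probe is required")
    if (anyDuplicated(object@probes))
        msg <- c(msg, "feature probes must be unique")
    if (length(msg)) msg else TRUE
})
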