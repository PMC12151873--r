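#' Configure the synthetic two-cohort methylome generator
#'
#' Defaults emulate the rewilding study design: 20 laboratory and 41 field
#' liver samples aged 26-225 days, field aging rates 94% faster at
#' hypermethylating sites and 28% faster at hypomethylating sites, and a
#' probe-class mix in which roughly one probe in ten carries an age signal.
#'
#' @param nProbes number of probes.
#' @param nLab,nField cohort sample counts.
#' @param ageRangeDays length-2 numeric, (min, max) age in days.
#' @param classFractions named proportions over
#'   `hyper`/`hypo`/`null`/`sex_linked`; must sum to 1.
#' @param slopeScalePerYear half-normal scale of baseline (lab) aging rates,
#'   methylation fraction per year.
#' @param rateRatioHyper,rateRatioHypo multipliers applied to field slopes at
#'   hyper- and hypomethylating probes.
#' @param sexEffect male-vs-female beta offset at sex-linked probes.
#' @param noiseSd beta-scale Gaussian noise standard deviation.
#' @param missingRate independent per-cell missing probability in \[0, 1).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return A validated \linkS4class{SimConfig}.
#' @export
SimConfig <- function(nProbes = 20000L, nLab = 20L, nField = 41L,
                      ageRangeDays = c(26, 225),
                      classFractions = c(hyper = 0.06, hypo = 0.04,
                                         null = 0.89, sex_linked = 0.01),
                      slopeScalePerYear = 0.1,
                      rateRatioHyper = 1.94, rateRatioHypo = 1.28,
                      sexEffect = 0.15, noiseSd = 0.02,
                      missingRate = 0.03, seed = 1L) {
    new("SimConfig",
        nProbes = as.integer(nProbes), nLab = as.integer(nLab),
        nField = as.integer(nField), ageRangeDays = as.numeric(ageRangeDays),
        classFractions = classFractions,
        slopeScalePerYear = slopeScalePerYear,
        rateRatioHyper = rateRatioHyper, rateRatioHypo = rateRatioHypo,
        sexEffect = sexEffect, noiseSd = noiseSd,
        missingRate = missingRate, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nProbes, "probes;",
        object@nLab, "lab +", object@nField, "field samples; ages",
        paste(object@ageRangeDays, collapse = "-"), "days\n")
    cat("  class fractions:",
        paste(sprintf("%s=%.3g", names(object@classFractions),
                      object@classFractions), collapse = ", "), "\n")
    cat(sprintf("  rate ratios: hyper %.3g, hypo %.3g; noise sd %.3g; missing %.3g\n",
                object@rateRatioHyper, object@rateRatioHypo,
                object@noiseSd, object@missingRate))
})

# Exact per-class probe counts: cumulative rounding guarantees the counts
# sum to nProbes and reproduce exact products (e.g. 25% of 1000 -> 250).
.classCounts <- function(nProbes, fractions) {
    fractions <- fractions[c("hyper", "hypo", "null", "sex_linked")]
    cuts <- round(cumsum(fractions) * nProbes)
    counts <- diff(c(0, cuts))
    names(counts) <- names(fractions)
    counts
}

#' Simulate two-cohort aging methylomes with known per-site truth
#'
#' Each probe belongs to one of four classes.  `hyper` probes gain
#' methylation with age in both cohorts (field slope = lab slope times
#' `rateRatioHyper`), `hypo` probes lose it (multiplier `rateRatioHypo`),
#' `null` probes have zero slope, and `sex_linked` probes sit on the X or Y
#' chromosome with a male-vs-female offset and zero age slope.  The observed
#' beta is
#' `clamp(baseline + slope(env) * age_years + sexEffect * I(male) + noise, 0, 1)`
#' with Gaussian beta-scale noise, after which cells go missing independently
#' at `missingRate`.  Baselines are uniform on \[0.2, 0.8\], restricted to
#' \[0.2, 0.5\] at hyper and \[0.5, 0.8\] at hypo probes (gaining sites start
#' lowly methylated and vice versa) so trajectories stay clear of the clamp;
#' ages are uniform over the configured range and sexes alternate within
#' each cohort.  Probe classes are assigned in
#' deterministic index blocks so truth-table class counts are exact.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with elements `betas` (a \linkS4class{BetaSet} carrying
#'   sample sheet and probe annotation) and `truth` (a
#'   [S4Vectors::DataFrame] with per-probe class, true lab and field slopes
#'   per year, chromosome and baseline).
#' @examples
#' sim <- simulateCohorts(SimConfig(nProbes = 100, seed = 7))
#' sim$betas
#' @export
simulateCohorts <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    nP <- config@nProbes
    nS <- config@nLab + config@nField

    counts <- .classCounts(nP, config@classFractions)
    classes <- rep(names(counts), counts)
    probeIds <- sprintf("cg%07d", seq_len(nP))

    # truth: half-normal lab slopes, scaled field slopes, zero for null/sex
    labSlope <- numeric(nP)
    fieldSlope <- numeric(nP)
    isHyper <- classes == "hyper"
    isHypo <- classes == "hypo"
    labSlope[isHyper] <- abs(rnorm(sum(isHyper), 0, config@slopeScalePerYear))
    labSlope[isHypo] <- -abs(rnorm(sum(isHypo), 0, config@slopeScalePerYear))
    fieldSlope[isHyper] <- config@rateRatioHyper * labSlope[isHyper]
    fieldSlope[isHypo] <- config@rateRatioHypo * labSlope[isHypo]

    chrom <- paste0("chr", rep_len(1:19, nP))
    isSex <- classes == "sex_linked"
    chrom[isSex] <- rep_len(c("X", "Y"), sum(isSex))
    # hyper sites start lowly methylated, hypo sites highly methylated, so
    # trajectories stay clear of the [0,1] clamp at realistic rates
    baseline <- runif(nP, 0.2, 0.8)
    baseline[isHyper] <- runif(sum(isHyper), 0.2, 0.5)
    baseline[isHypo] <- runif(sum(isHypo), 0.5, 0.8)

    sampleIds <- c(sprintf("lab%03d", seq_len(config@nLab)),
                   sprintf("field%03d", seq_len(config@nField)))
    envs <- rep(ENV_LEVELS, c(config@nLab, config@nField))
    ages <- c(runif(config@nLab, config@ageRangeDays[1], config@ageRangeDays[2]),
              runif(config@nField, config@ageRangeDays[1], config@ageRangeDays[2]))
    sexes <- c(rep_len(SEX_LEVELS, config@nLab),
               rep_len(SEX_LEVELS, config@nField))
    ageYears <- ages / DAYS_PER_YEAR
    male <- as.numeric(sexes == "M")

    slopes <- cbind(lab = labSlope, field = fieldSlope)
    slopeUsed <- slopes[, ifelse(envs == "lab", 1L, 2L), drop = FALSE]
    mu <- baseline +
        slopeUsed * rep(ageYears, each = nP) +
        (isSex * config@sexEffect) %o% male
    beta <- mu
    if (config@noiseSd > 0)
        beta <- beta + matrix(rnorm(nP * nS, 0, config@noiseSd), nP, nS)
    beta <- pmin(pmax(beta, 0), 1)
    if (config@missingRate > 0)
        beta[matrix(runif(nP * nS) < config@missingRate, nP, nS)] <- NA_real_
    dimnames(beta) <- list(probeIds, sampleIds)

    sheet <- data.frame(
        sample_id = sampleIds, age_days = ages, sex = sexes,
        environment = envs,
        exposure_group = ifelse(envs == "lab", "lab", "field_infant"),
        stringsAsFactors = FALSE)
    anno <- data.frame(probe_id = probeIds, chrom = chrom,
                       probe_class = "cg", stringsAsFactors = FALSE)
    truth <- S4Vectors::DataFrame(
        probe_id = probeIds, class = classes,
        slope_lab_per_year = labSlope, slope_field_per_year = fieldSlope,
        chrom = chrom, baseline = baseline, row.names = probeIds)
    list(betas = BetaSet(beta, sheet, anno), truth = truth)
}
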