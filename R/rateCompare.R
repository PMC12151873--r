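#' Categorize probes by joint significance and slope direction
#'
#' Deterministic mapping from the two per-environment fits at a strict
#' q-value threshold: jointly significant probes split by slope-sign pattern
#' (`joint_hyper`, `joint_hypo`, `field_up_lab_down`, `field_down_lab_up`),
#' singly significant probes into `lab_only_sig`/`field_only_sig`, the rest
#' `not_significant`.  The "age-associated in at least one environment" set
#' is exactly the complement of `not_significant`.
#'
#' @param lab,field \linkS4class{SiteWiseFit}s over the same probe universe.
#' @param qThresh strict (<) q-value cutoff, default 0.01.
#' @return [S4Vectors::DataFrame] with per-probe slopes, q-values,
#'   significance flags and a `category` factor.
#' @export
categorizeSites <- function(lab, field, qThresh = 0.01) {
    stopifnot(is(lab, "SiteWiseFit"), is(field, "SiteWiseFit"))
    rl <- fitResults(lab)
    rf <- fitResults(field)
    if (!identical(rl$probe_id, rf$probe_id))
        stop("lab and field fits must share the same probe universe")
    sigLab <- !is.na(rl$q_age) & rl$q_age < qThresh
    sigField <- !is.na(rf$q_age) & rf$q_age < qThresh
    sl <- rl$slope_per_year
    sf <- rf$slope_per_year
    category <- rep("not_significant", nrow(rl))
    category[sigLab & !sigField] <- "lab_only_sig"
    category[!sigLab & sigField] <- "field_only_sig"
    both <- sigLab & sigField
    category[both & sl > 0 & sf > 0] <- "joint_hyper"
    category[both & sl < 0 & sf < 0] <- "joint_hypo"
    category[both & sl < 0 & sf > 0] <- "field_up_lab_down"
    category[both & sl > 0 & sf < 0] <- "field_down_lab_up"
    S4Vectors::DataFrame(
        probe_id = rl$probe_id,
        slope_lab = sl, slope_field = sf,
        q_lab = rl$q_age, q_field = rf$q_age,
        sig_lab = sigLab, sig_field = sigField,
        category = factor(category, levels = SITE_CATEGORIES),
        row.names = rl$probe_id)
}

#' Octant of (lab, field) slope pairs
#'
#' 45-degree sectors of the rate plane numbered 1-8 counterclockwise from
#' the positive lab axis, half-open `[(k-1)*45, k*45)` so boundary angles
#' belong to the upper sector; exact `(0, 0)` pairs give `NA`.
#'
#' @param labSlopes,fieldSlopes numeric aging rates.
#' @return integer octants in 1-8, `NA` at the origin.
#' @export
octantOf <- function(labSlopes, fieldSlopes) {
    ang <- atan2(fieldSlopes, labSlopes) * 180 / pi
    ang <- ang %% 360
    oct <- as.integer(floor(ang / 45)) + 1L
    oct[oct > 8L] <- 1L   # guard against ang == 360 from rounding
    oct[labSlopes == 0 & fieldSlopes == 0] <- NA_integer_
    oct
}

#' Octant summary of lab-versus-field aging rate pairs
#'
#' Assigns each slope pair to one of eight evenly spaced 45-degree angular
#' sectors of the (lab rate, field rate) plane, counterclockwise from the
#' positive lab axis with half-open boundaries, and tabulates counts and
#' percentages.  Octants 1-2 cover joint gains (octant 2 = faster in the
#' field), octants 5-6 joint losses (octant 6 = faster in the field, i.e.
#' more negative), octants 3-4 field-up/lab-down, octants 7-8 the reverse.
#' Exact (0,0) pairs are excluded.
#'
#' @param labSlopes,fieldSlopes numeric aging rates per probe.
#' @param mask logical or integer index of probes to summarize (e.g. the
#'   age-associated set); default all.
#' @return data.frame with columns `octant`, `count`, `percent`, plus the
#'   total in attribute `n_total`.
#' @export
octantSummary <- function(labSlopes, fieldSlopes,
                          mask = seq_along(labSlopes)) {
    x <- labSlopes[mask]
    y <- fieldSlopes[mask]
    if (!length(x)) stop("empty mask")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("slope pairs must be finite")
    oct <- octantOf(x, y)
    oct <- oct[!is.na(oct)]
    if (!length(oct)) stop("no nonzero slope pairs in mask")
    counts <- tabulate(oct, nbins = 8L)
    out <- data.frame(octant = 1:8, count = counts,
                      percent = 100 * counts / sum(counts))
    attr(out, "n_total") <- sum(counts)
    out
}

#' Zero-intercept field-versus-lab rate ratio
#'
#' Regression of field aging rates on lab aging rates through the origin:
#' `ratio = sum(x*y) / sum(x^2)`.  The 95% confidence interval uses the
#' classical no-intercept OLS standard error with `n - 1` residual degrees
#' of freedom; a nonparametric site-resampling bootstrap (percentile CI) is
#' available as an alternative.
#'
#' @param labSlopes,fieldSlopes numeric aging rates per probe.
#' @param mask probes to use, typically a jointly significant set.
#' @param ciMethod `"normal"` (default) or `"bootstrap"`.
#' @param nBoot bootstrap replicates when `ciMethod = "bootstrap"`.
#' @param conf confidence level, default 0.95.
#' @return A \linkS4class{RateRatio}.
#' @examples
#' zeroInterceptRatio(c(1, 2), c(2, 2))  # ratio = 6/5
#' @export
zeroInterceptRatio <- function(labSlopes, fieldSlopes,
                               mask = seq_along(labSlopes),
                               ciMethod = c("normal", "bootstrap"),
                               nBoot = 2000L, conf = 0.95) {
    ciMethod <- match.arg(ciMethod)
    x <- labSlopes[mask]
    y <- fieldSlopes[mask]
    n <- length(x)
    if (n < 2L) stop("rate ratio requires >= 2 sites")
    sxx <- sum(x * x)
    if (sxx == 0) stop("undefined ratio: all lab slopes in mask are zero")
    ratio <- sum(x * y) / sxx
    if (ciMethod == "normal") {
        rss <- sum((y - ratio * x)^2)
        se <- sqrt(rss / (n - 1) / sxx)
        tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
        ci <- ratio + c(-1, 1) * tq * se
    } else {
        reps <- vapply(seq_len(nBoot), function(i) {
            idx <- sample.int(n, n, replace = TRUE)
            sum(x[idx] * y[idx]) / sum(x[idx]^2)
        }, numeric(1))
        ci <- unname(stats::quantile(reps, c((1 - conf) / 2,
                                             1 - (1 - conf) / 2)))
    }
    new("RateRatio", ratio = ratio, ciLow = ci[1], ciHigh = ci[2],
        nSites = as.integer(n), ciMethod = ciMethod)
}

#' @describeIn zeroInterceptRatio percentage by which field rates exceed lab
#'   rates, `(ratio - 1) * 100`
#' @param object a \linkS4class{RateRatio}
#' @export
pctFaster <- function(object) (object@ratio - 1) * 100

#' @describeIn zeroInterceptRatio extract ratio, CI and site count as a
#'   one-row data.frame
#' @export
rateRatioTable <- function(object) {
    data.frame(ratio = object@ratio, ci_low = object@ciLow,
               ci_high = object@ciHigh, pct_faster = pctFaster(object),
               n_sites = object@nSites)
}

setMethod("show", "RateRatio", function(object) {
    cat(sprintf("RateRatio: %.4g (95%% CI %.4g-%.4g, %s), n = %d sites\n",
                object@ratio, object@ciLow, object@ciHigh,
                object@ciMethod, object@nSites))
    cat(sprintf("  field rates %.1f%% %s than lab\n", abs(pctFaster(object)),
                if (pctFaster(object) >= 0) "faster" else "slower"))
})

#' Spearman concordance of aging rates between environments
#'
#' Rank correlation (average-rank ties) with a large-sample p-value.
#'
#' @inheritParams zeroInterceptRatio
#' @return list with `rho`, `p`, `n`.
#' @export
rateConcordance <- function(labSlopes, fieldSlopes,
                            mask = seq_along(labSlopes)) {
    x <- labSlopes[mask]
    y <- fieldSlopes[mask]
    if (length(x) < 3L) stop("concordance requires >= 3 sites")
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
        stop("undefined correlation: constant slope vector")
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Count interaction-significant sites aging faster in the field
#'
#' Among jointly significant hyper- (resp. hypo-) methylating sites whose
#' age-by-environment interaction is significant at `qIntThresh`, counts the
#' sites whose field rate is faster in absolute terms: interaction
#' coefficient (field minus lab slope) positive at hyper sites, negative at
#' hypo sites.
#'
#' @param categories output of [categorizeSites()].
#' @param inter an \linkS4class{InteractionFit} on the same probe universe.
#' @param qIntThresh strict q cutoff on the interaction term, default 0.05.
#' @return data.frame with one row per joint category: `n_faster_field`,
#'   `n_total` (interaction-significant sites), `percent` (`NA` when the
#'   set is empty).
#' @export
countInteractionDirections <- function(categories, inter,
                                       qIntThresh = 0.05) {
    stopifnot(is(inter, "InteractionFit"))
    ri <- fitResults(inter)
    if (!identical(categories$probe_id, ri$probe_id))
        stop("categories and interaction fit must share the probe universe")
    sigInt <- !is.na(ri$q_int) & ri$q_int < qIntThresh
    rows <- lapply(c(joint_hyper = "joint_hyper", joint_hypo = "joint_hypo"),
                   function(cat) {
        inCat <- categories$category == cat & sigInt
        n <- sum(inCat)
        faster <- if (cat == "joint_hyper")
            sum(inCat & ri$age_env_coef > 0, na.rm = TRUE)
        else
            sum(inCat & ri$age_env_coef < 0, na.rm = TRUE)
        data.frame(category = cat, n_faster_field = faster, n_total = n,
                   percent = if (n > 0) 100 * faster / n else NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
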