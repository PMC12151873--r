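#' Benjamini-Hochberg adjusted q-values
#'
#' Thin validated wrapper around the step-up false discovery rate procedure
#' (`stats::p.adjust(method = "BH")`): q(i) = min over j >= i of
#' p(j) * m / j, capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]; `NA` not allowed.
#' @return q-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(pvals) {
    if (!is.numeric(pvals) || anyNA(pvals) ||
        any(pvals < 0 | pvals > 1))
        stop("p-values must be numeric in [0, 1] with no NA")
    stats::p.adjust(pvals, method = "BH")
}

# Grouped least squares over probes sharing a missingness pattern.
# Y: probes x samples (this group's complete columns), X: samples x k.
# Returns coefficient/se matrices (k x probes, NA for aliased columns),
# residual df, and a zero-residual flag used for degenerate p-values.
.olsGroup <- function(Y, X) {
    n <- ncol(Y)
    k <- ncol(X)
    qx <- qr(X)
    r <- qx$rank
    keep <- qx$pivot[seq_len(r)]
    Xr <- X[, keep, drop = FALSE]
    xtxi <- chol2inv(qr.R(qr(Xr)))
    cf <- xtxi %*% crossprod(Xr, t(Y))            # r x probes
    res <- t(Y) - Xr %*% cf
    rss <- colSums(res * res)
    df <- n - r
    zeroResid <- rss < n * 1e-24
    s2 <- if (df > 0) rss / df else rep(NA_real_, ncol(res))
    se <- sqrt(outer(diag(xtxi), s2))             # r x probes
    coef <- matrix(NA_real_, k, nrow(Y))
    sem <- matrix(NA_real_, k, nrow(Y))
    coef[keep, ] <- cf
    sem[keep, ] <- se
    list(coef = coef, se = sem, df = df, zeroResid = zeroResid)
}

# Two-sided t-test p-values with the degenerate-fit convention: an exactly
# interpolating model gives p = 0 for a nonzero coefficient and p = 1 for a
# zero one, so noiseless fixtures never produce NaN.
.tPvalue <- function(coef, se, df, zeroResid) {
    p <- 2 * stats::pt(-abs(coef / se), df)
    deg <- zeroResid | (!is.na(se) & se == 0)
    p[deg & !is.na(coef) & abs(coef) > 1e-12] <- 0
    p[deg & !is.na(coef) & abs(coef) <= 1e-12] <- 1
    if (df <= 0) p[] <- NA_real_
    p
}

# Massively parallel complete-case OLS: probes are grouped by missingness
# pattern so the all-observed majority is solved in one matrix operation.
# X: samples x k design. Returns per-probe coef/se/p for requested columns.
.fitProbewise <- function(beta, X, testCols) {
    nP <- nrow(beta)
    k <- ncol(X)
    out <- list(
        n_used = integer(nP),
        coef = matrix(NA_real_, nP, k),
        se = matrix(NA_real_, nP, k),
        p = matrix(NA_real_, nP, k),
        df = rep(NA_real_, nP))
    obs <- !is.na(beta)
    out$n_used <- as.integer(rowSums(obs))
    fitRows <- which(out$n_used >= k + 1L)
    if (!length(fitRows)) return(out)
    complete <- fitRows[rowSums(obs[fitRows, , drop = FALSE]) == ncol(beta)]
    partial <- setdiff(fitRows, complete)
    groups <- list()
    if (length(complete))
        groups[[1]] <- list(rows = complete, use = rep(TRUE, ncol(beta)))
    if (length(partial)) {
        key <- apply(obs[partial, , drop = FALSE], 1L, paste, collapse = "")
        for (pat in unique(key)) {
            rows <- partial[key == pat]
            groups[[length(groups) + 1L]] <-
                list(rows = rows, use = obs[rows[1], ])
        }
    }
    for (g in groups) {
        Xs <- X[g$use, , drop = FALSE]
        Ys <- beta[g$rows, g$use, drop = FALSE]
        fit <- .olsGroup(Ys, Xs)
        out$coef[g$rows, ] <- t(fit$coef)
        out$se[g$rows, ] <- t(fit$se)
        for (j in testCols)
            out$p[g$rows, j] <- .tPvalue(fit$coef[j, ], fit$se[j, ],
                                         fit$df, fit$zeroResid)
        out$df[g$rows] <- fit$df
    }
    out
}

# Probes are reordered to a canonical sample order (sorted sample ids)
# before fitting so that results are bit-identical under input permutation.
.canonicalOrder <- function(ids) order(ids)

#' Fit per-probe age + sex models within one environment
#'
#' For every probe, ordinary least squares of beta on
#' `[intercept, age_years, male]` over that probe's complete cases within
#' the requested environment, with exact t-tests (df = n_used - columns) on
#' the age and sex coefficients and BH q-values across all probes passing
#' the missingness filter.  Age is converted from days to years
#' (days / 365.25) so slopes are the per-year epigenetic aging rates.
#'
#' @param betas a \linkS4class{BetaSet}.
#' @param environment `"lab"` or `"field"`.
#' @param maxMissing probes whose missing fraction (within the environment)
#'   exceeds this are excluded from fitting and inference (default 0.2).
#' @param includeSex include the male indicator covariate (default TRUE).
#' @return A \linkS4class{SiteWiseFit}.
#' @export
fitAgeModel <- function(betas, environment = c("lab", "field"),
                        maxMissing = 0.2, includeSex = TRUE) {
    environment <- match.arg(environment)
    env <- sampleEnvironment(betas)
    sel <- which(env == environment)
    if (length(sel) < 4L)
        stop("need >= 4 samples in environment '", environment, "'")
    sel <- sel[.canonicalOrder(colnames(betas)[sel])]
    b <- betaValues(betas)[, sel, drop = FALSE]
    ageYears <- sampleAges(betas)[sel] / DAYS_PER_YEAR
    male <- as.numeric(sampleSex(betas)[sel] == "M")
    X <- if (includeSex) cbind(intercept = 1, age = ageYears, male = male)
         else cbind(intercept = 1, age = ageYears)
    ageCol <- 2L
    sexCol <- if (includeSex) 3L else NA_integer_

    filtered <- rowMeans(is.na(b)) > maxMissing
    bFit <- b
    bFit[filtered, ] <- NA_real_
    fit <- .fitProbewise(bFit, X, testCols = stats::na.omit(c(ageCol, sexCol)))

    tested <- !is.na(fit$p[, ageCol])
    qAge <- qSex <- rep(NA_real_, nrow(b))
    qAge[tested] <- bhAdjust(fit$p[tested, ageCol])
    if (includeSex) {
        sexTested <- !is.na(fit$p[, sexCol])
        qSex[sexTested] <- bhAdjust(fit$p[sexTested, sexCol])
    }
    res <- S4Vectors::DataFrame(
        probe_id = rownames(b),
        n_used = as.integer(rowSums(!is.na(b))),
        filtered = filtered,
        slope_per_year = fit$coef[, ageCol],
        slope_se = fit$se[, ageCol],
        p_age = fit$p[, ageCol],
        q_age = qAge,
        sex_coef = if (includeSex) fit$coef[, sexCol] else NA_real_,
        p_sex = if (includeSex) fit$p[, sexCol] else NA_real_,
        q_sex = qSex,
        row.names = rownames(b))
    new("SiteWiseFit", results = res, modelEnvironment = environment,
        nSamples = length(sel), maxMissing = maxMissing)
}

#' Fit the per-probe age-by-environment interaction model
#'
#' For every probe, OLS of beta on
#' `[intercept, age_years, field, age_years x field (, male)]` over complete
#' cases pooled across both cohorts.  The interaction coefficient
#' `age_env_coef` is the field-minus-lab difference in aging rate
#' (fraction/year, lab as reference); its two-sided t-test p-values receive
#' BH adjustment across tested probes.
#'
#' @inheritParams fitAgeModel
#' @param includeSex adjust for sex (default TRUE).
#' @return An \linkS4class{InteractionFit}.
#' @export
fitInteractionModel <- function(betas, maxMissing = 0.2, includeSex = TRUE) {
    env <- sampleEnvironment(betas)
    if (length(unique(env)) < 2L)
        stop("interaction model requires both environments; found only '",
             unique(env), "'")
    if (min(table(env)) < 4L)
        stop("need >= 4 samples per environment")
    sel <- .canonicalOrder(colnames(betas))
    b <- betaValues(betas)[, sel, drop = FALSE]
    ageYears <- sampleAges(betas)[sel] / DAYS_PER_YEAR
    field <- as.numeric(env[sel] == "field")
    male <- as.numeric(sampleSex(betas)[sel] == "M")
    X <- cbind(intercept = 1, age = ageYears, field = field,
               age_field = ageYears * field)
    if (includeSex) X <- cbind(X, male = male)
    intCol <- 4L

    filtered <- rowMeans(is.na(b)) > maxMissing
    bFit <- b
    bFit[filtered, ] <- NA_real_
    fit <- .fitProbewise(bFit, X, testCols = intCol)

    tested <- !is.na(fit$p[, intCol])
    qInt <- rep(NA_real_, nrow(b))
    qInt[tested] <- bhAdjust(fit$p[tested, intCol])
    res <- S4Vectors::DataFrame(
        probe_id = rownames(b),
        n_used = as.integer(rowSums(!is.na(b))),
        filtered = filtered,
        age_coef = fit$coef[, 2L],
        age_env_coef = fit$coef[, intCol],
        interaction_se = fit$se[, intCol],
        p_int = fit$p[, intCol],
        q_int = qInt,
        row.names = rownames(b))
    new("InteractionFit", results = res, nSamples = ncol(b),
        maxMissing = maxMissing, sexAdjusted = includeSex)
}

#' Extract the per-probe result table from a fit object
#' @param x a \linkS4class{SiteWiseFit} or \linkS4class{InteractionFit}
#' @return a [S4Vectors::DataFrame] with one row per probe
#' @export
setGeneric("fitResults", function(x) standardGeneric("fitResults"))

#' @rdname fitResults
#' @export
setMethod("fitResults", "SiteWiseFit", function(x) x@results)

#' @rdname fitResults
#' @export
setMethod("fitResults", "InteractionFit", function(x) x@results)

#' Named vector of per-probe epigenetic aging rates (fraction/year)
#' @param x a \linkS4class{SiteWiseFit}
#' @export
agingRates <- function(x) {
    stopifnot(is(x, "SiteWiseFit"))
    r <- x@results$slope_per_year
    names(r) <- x@results$probe_id
    r
}

#' Environment a SiteWiseFit was computed in
#' @param x a \linkS4class{SiteWiseFit}
#' @export
modelEnvironment <- function(x) x@modelEnvironment

setMethod("show", "SiteWiseFit", function(object) {
    r <- object@results
    cat(sprintf("SiteWiseFit (%s): %d probes, %d samples\n",
                object@modelEnvironment, nrow(r), object@nSamples))
    ok <- !is.na(r$q_age)
    cat(sprintf("  tested: %d; q_age < 0.01: %d\n",
                sum(ok), sum(r$q_age < 0.01, na.rm = TRUE)))
})

setMethod("show", "InteractionFit", function(object) {
    r <- object@results
    cat(sprintf("InteractionFit: %d probes, %d samples (sex-adjusted: %s)\n",
                nrow(r), object@nSamples, object@sexAdjusted))
    cat(sprintf("  tested: %d; q_int < 0.05: %d\n",
                sum(!is.na(r$q_int)), sum(r$q_int < 0.05, na.rm = TRUE)))
})
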