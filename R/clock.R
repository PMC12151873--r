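#' Train an elastic-net epigenetic clock on autosomal probes
#'
#' Fits a penalized linear model of chronological age in months
#' (days / 30.44) on methylation fractions, restricted to autosomal probes
#' (chromosome not X/Y/MT).  Features are standardized internally and
#' coefficients returned on the beta scale.  When `lambda` is `NULL` the
#' penalty is chosen on a lambda path by k-fold cross-validation minimizing
#' mean absolute error, with folds drawn reproducibly from `seed`.  Missing
#' betas are imputed with per-probe training means, which are stored in the
#' model for prediction-time imputation.
#'
#' @param betas a \linkS4class{BetaSet} with chromosome annotation.
#' @param alpha elastic-net mixing parameter in \[0, 1\], default 0.5.
#' @param nFolds cross-validation folds, default 10.
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation.
#' @return A \linkS4class{ClockModel} storing only nonzero-weight features.
#' @export
trainClock <- function(betas, alpha = 0.5, nFolds = 10L, seed = 1L,
                       lambda = NULL) {
    auto <- isAutosomal(betas)
    if (!any(auto))
        stop("no autosomal probes available as clock features")
    n <- ncol(betas)
    if (is.null(lambda) && nFolds > n)
        stop("nFolds exceeds the number of training samples")
    if (is.null(lambda) && n < 2L * nFolds)
        stop("need at least 2 samples per cross-validation fold")
    ageMonths <- sampleAges(betas) / DAYS_PER_MONTH
    b <- betaValues(betas)[auto, , drop = FALSE]
    rowMu <- rowMeans(b, na.rm = TRUE)
    keep <- is.finite(rowMu)
    b <- b[keep, , drop = FALSE]
    rowMu <- rowMu[keep]
    naIdx <- which(is.na(b), arr.ind = TRUE)
    if (nrow(naIdx)) b[naIdx] <- rowMu[naIdx[, 1]]
    x <- t(b)

    if (is.null(lambda)) {
        set.seed(seed)
        foldid <- sample(rep_len(seq_len(nFolds), n))
        cv <- glmnet::cv.glmnet(x, ageMonths, alpha = alpha,
                                type.measure = "mae", foldid = foldid)
        lambda <- cv$lambda.min
        fit <- cv$glmnet.fit
    } else {
        fit <- glmnet::glmnet(x, ageMonths, alpha = alpha)
    }
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = x,
                                y = ageMonths, alpha = alpha))
    intercept <- cf[1, 1]
    w <- cf[-1, 1]
    nz <- which(w != 0)
    new("ClockModel",
        probes = rownames(b)[nz], weights = unname(w[nz]),
        intercept = intercept, featureMeans = unname(rowMu[nz]),
        alpha = alpha, lambda = lambda, nFolds = as.integer(nFolds),
        seed = as.integer(seed), nTrain = as.integer(n))
}

#' @describeIn trainClock feature probe ids with nonzero weight
#' @param object a \linkS4class{ClockModel}
#' @export
clockFeatures <- function(object) object@probes

#' @describeIn trainClock named vector of feature weights
#'   (methylation fraction to months)
#' @export
clockWeights <- function(object) {
    w <- object@weights
    names(w) <- object@probes
    w
}

#' @describeIn trainClock model intercept in months
#' @export
clockIntercept <- function(object) object@intercept

setMethod("show", "ClockModel", function(object) {
    cat(sprintf(
        "ClockModel: %d features (alpha = %.3g, lambda = %.4g, %d-fold CV)\n",
        length(object@probes), object@alpha, object@lambda, object@nFolds))
    cat(sprintf("  intercept %.3g months; trained on %d samples (seed %d)\n",
                object@intercept, object@nTrain, object@seed))
})

#' Predict epigenetic age and residuals with a clock
#'
#' Linear prediction `intercept + sum(weight * beta)` per sample.  Features
#' missing from a sample are imputed with their stored training means;
#' samples with more than 20% of features missing are flagged.  When
#' chronological ages are available, residuals (predicted minus
#' chronological, months) are attached.
#'
#' @param model a \linkS4class{ClockModel}.
#' @param betas a \linkS4class{BetaSet}; probes absent from the matrix count
#'   as missing for every sample.
#' @return [S4Vectors::DataFrame] with one row per sample: predicted and
#'   chronological age (months), `residual_months`, the fraction of
#'   imputed features and a `high_missing` flag, plus `environment` when
#'   present in the column data.
#' @export
predictAge <- function(model, betas) {
    stopifnot(is(model, "ClockModel"))
    b <- betaValues(betas)
    k <- length(model@probes)
    feat <- matrix(NA_real_, k, ncol(b),
                   dimnames = list(model@probes, colnames(b)))
    present <- intersect(model@probes, rownames(b))
    feat[present, ] <- b[present, , drop = FALSE]
    fracMissing <- if (k > 0) colMeans(is.na(feat)) else rep(0, ncol(b))
    naIdx <- which(is.na(feat), arr.ind = TRUE)
    if (nrow(naIdx)) feat[naIdx] <- model@featureMeans[naIdx[, 1]]
    pred <- model@intercept +
        if (k > 0) drop(crossprod(feat, model@weights)) else 0
    ageMonths <- sampleAges(betas) / DAYS_PER_MONTH
    out <- S4Vectors::DataFrame(
        sample_id = colnames(b),
        predicted_months = unname(rep_len(pred, ncol(b))),
        age_months = unname(ageMonths),
        residual_months = unname(rep_len(pred, ncol(b)) - ageMonths),
        frac_features_missing = unname(fracMissing),
        high_missing = unname(fracMissing > 0.2),
        row.names = colnames(b))
    cd <- SummarizedExperiment::colData(betas)
    if ("environment" %in% colnames(cd))
        out$environment <- as.character(cd$environment)
    if (any(out$high_missing))
        warning(sum(out$high_missing),
                " sample(s) had > 20% of clock features missing")
    out
}

#' Compare clock residuals between environments
#'
#' Per-environment median residuals (predicted minus chronological age,
#' months) and a two-sided test of the field-versus-lab residual
#' distributions: Wilcoxon rank-sum by default, Welch t-test by flag.
#'
#' @param pred output of [predictAge()] including an `environment` column
#'   (or supply `environment` explicitly).
#' @param environment optional per-sample `"lab"`/`"field"` vector
#'   overriding the column in `pred`.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list with `median_field`, `median_lab`,
#'   `median_difference` (field minus lab), `p`, `n_field`, `n_lab`,
#'   `test`.
#' @export
compareResiduals <- function(pred, environment = NULL,
                             test = c("wilcoxon", "t")) {
    test <- match.arg(test)
    env <- if (!is.null(environment)) environment else pred$environment
    if (is.null(env))
        stop("no environment labels available")
    res <- pred$residual_months
    fieldRes <- res[env == "field"]
    labRes <- res[env == "lab"]
    if (length(fieldRes) < 3L || length(labRes) < 3L)
        stop("both environments need >= 3 samples with residuals")
    ht <- if (test == "wilcoxon")
        suppressWarnings(stats::wilcox.test(fieldRes, labRes,
                                            alternative = "two.sided"))
    else
        stats::t.test(fieldRes, labRes)
    list(median_field = stats::median(fieldRes),
         median_lab = stats::median(labRes),
         median_difference = stats::median(fieldRes) - stats::median(labRes),
         p = ht$p.value, n_field = length(fieldRes), n_lab = length(labRes),
         test = test)
}
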