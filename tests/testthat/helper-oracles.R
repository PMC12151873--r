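# Independent oracles used across tests. These deliberately take the naive
# route (per-probe lm(), explicit step-up, direct tail summation) so they
# share no code with the package implementation.

# Benjamini-Hochberg step-up by its definition: q(i) = min_{j >= i} p(j)*m/j
# on the sorted p-values, capped at 1, mapped back to input order.
bhStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- ps * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Per-probe naive OLS refit with stats::lm on complete cases.
lmOracle <- function(beta, age_years, male = NULL, term = "age_years") {
    t(vapply(seq_len(nrow(beta)), function(i) {
        df <- data.frame(y = beta[i, ], age_years = age_years)
        if (!is.null(male)) df$male <- male
        df <- df[stats::complete.cases(df), , drop = FALSE]
        fit <- stats::lm(y ~ ., data = df)
        cf <- suppressWarnings(summary(fit))$coefficients
        if (!(term %in% rownames(cf)))
            return(c(est = NA_real_, se = NA_real_, p = NA_real_))
        c(est = cf[term, 1], se = cf[term, 2], p = cf[term, 4])
    }, numeric(3)))
}

# Angle-based octant oracle: explicit sector comparison on the angle in
# degrees measured counterclockwise from the positive lab axis.
octantOracle <- function(lab, field) {
    vapply(seq_along(lab), function(i) {
        if (lab[i] == 0 && field[i] == 0) return(NA_integer_)
        ang <- atan2(field[i], lab[i]) * 180 / pi
        if (ang < 0) ang <- ang + 360
        for (k in 1:8)
            if (ang >= (k - 1) * 45 && ang < k * 45) return(k)
        1L  # ang == 360 after rounding
    }, integer(1))
}

# Hypergeometric upper tail P(X >= a) by direct summation of dhyper.
hyperTailOracle <- function(a, nSet, nUniverse, nQuery) {
    ks <- a:min(nSet, nQuery)
    if (a > min(nSet, nQuery)) return(0)
    sum(stats::dhyper(ks, nSet, nUniverse - nSet, nQuery))
}

# Exact two-sided rank-sum p by enumerating all group assignments.
rankSumPermutationOracle <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    nx <- length(x)
    obs <- sum(r[seq_len(nx)])
    combos <- utils::combn(length(pooled), nx)
    stat <- apply(combos, 2, function(idx) sum(r[idx]))
    mu <- mean(stat)
    mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

# Small noiseless two-cohort fixture built directly (not via the
# generator) for cross-module tests.
makeNoiselessBetaSet <- function(nProbes = 20, nLab = 8, nField = 10,
                                 labSlopes = NULL, fieldSlopes = NULL,
                                 baseline = 0.4, seed = 42) {
    set.seed(seed)
    if (is.null(labSlopes)) labSlopes <- runif(nProbes, -0.1, 0.1)
    if (is.null(fieldSlopes)) fieldSlopes <- 1.5 * labSlopes
    ages <- round(seq(30, 220, length.out = nLab + nField))
    envs <- rep(c("lab", "field"), c(nLab, nField))
    sexes <- rep_len(c("F", "M"), nLab + nField)
    ageY <- ages / 365.25
    slopeUsed <- ifelse(envs == "lab",
                        rep(1, nLab + nField), rep(0, nLab + nField))
    beta <- outer(labSlopes, ageY * (envs == "lab")) +
        outer(fieldSlopes, ageY * (envs == "field")) + baseline
    stopifnot(all(beta >= 0 & beta <= 1))
    dimnames(beta) <- list(sprintf("p%03d", seq_len(nProbes)),
                           sprintf("s%03d", seq_len(nLab + nField)))
    sheet <- data.frame(sample_id = colnames(beta), age_days = ages,
                        sex = sexes, environment = envs)
    anno <- data.frame(probe_id = rownames(beta),
                       chrom = paste0("chr", rep_len(1:19, nProbes)),
                       probe_class = "cg")
    BetaSet(beta, sheet, anno)
}
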