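# Noiseless fixture where age in months is an exact linear function of 5
# autosomal probes; remaining probes are age-independent.
makeClockFixture <- function(nSamples = 40, nProbes = 60, seed = 19,
                             sexSignal = FALSE) {
    set.seed(seed)
    ages <- runif(nSamples, 26, 225)
    months <- ages / 30.44
    beta <- matrix(runif(nProbes * nSamples, 0.3, 0.7), nProbes, nSamples)
    # five informative probes, each linear in age and inside [0,1]
    w <- c(0.08, -0.06, 0.05, 0.07, -0.04)
    for (j in 1:5) beta[j, ] <- 0.5 + w[j] * (months - mean(months)) / 10
    dimnames(beta) <- list(sprintf("p%03d", 1:nProbes),
                           sprintf("s%03d", 1:nSamples))
    chrom <- paste0("chr", rep_len(1:19, nProbes))
    if (sexSignal) {
        chrom[6:10] <- "X"
        for (j in 6:10) beta[j, ] <- 0.5 + 0.05 * (months - mean(months)) / 10
    }
    sheet <- data.frame(sample_id = colnames(beta), age_days = ages,
                        sex = rep_len(c("F", "M"), nSamples),
                        environment = rep_len(c("lab", "field"), nSamples))
    anno <- data.frame(probe_id = rownames(beta), chrom = chrom,
                       probe_class = "cg")
    stopifnot(all(beta >= 0 & beta <= 1))
    BetaSet(beta, sheet, anno)
}
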