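test_that("noiseless linear age signal is recovered with near-zero MAE", {
    bs <- makeClockFixture(nSamples = 60)
    train <- bs[, 1:40]
    test <- bs[, 41:60]
    model <- trainClock(train, lambda = 1e-5, seed = 1)
    pred <- predictAge(model, test)
    mae <- mean(abs(pred$residual_months))
    expect_lt(mae, 0.1)
})

test_that("full shrinkage collapses to the training-mean predictor", {
    bs <- makeClockFixture(nSamples = 30)
    model <- trainClock(bs, lambda = 1e9, seed = 1)
    expect_length(clockFeatures(model), 0)
    pred <- predictAge(model, bs)
    meanAge <- mean(sampleAges(bs) / 30.44)
    expect_equal(unique(round(pred$predicted_months, 10)),
                 round(meanAge, 10))
})

test_that("sex-chromosome probes never enter the feature set", {
    bs <- makeClockFixture(nSamples = 40, sexSignal = TRUE)
    model <- trainClock(bs, lambda = 1e-5, seed = 1)
    chrom <- probeChromosome(bs)[clockFeatures(model)]
    expect_false(any(chrom %in% c("X", "Y")))
    # even with *only* sex-chromosome signal, features stay autosomal
    bsOnlySex <- bs
    noAuto <- makeClockFixture(nSamples = 40, sexSignal = TRUE)
    b <- betaValues(noAuto)
    b[1:5, ] <- 0.5  # erase the autosomal signal
    sheet <- as.data.frame(SummarizedExperiment::colData(noAuto))
    anno <- data.frame(probe_id = rownames(b),
                       chrom = probeChromosome(noAuto),
                       probe_class = "cg")
    onlySex <- BetaSet(b, sheet, anno)
    m2 <- trainClock(onlySex, lambda = 1e-4, seed = 1)
    expect_false(any(probeChromosome(onlySex)[clockFeatures(m2)] %in%
                     c("X", "Y")))
})

test_that("cross-validated training is reproducible and respects limits", {
    sim <- simulateCohorts(SimConfig(nProbes = 300, nLab = 24, nField = 4,
                                     seed = 41))
    m1 <- trainClock(sim$betas, nFolds = 6, seed = 5)
    m2 <- trainClock(sim$betas, nFolds = 6, seed = 5)
    expect_identical(clockWeights(m1), clockWeights(m2))
    expect_identical(m1@lambda, m2@lambda)
    expect_error(trainClock(sim$betas, nFolds = 30, seed = 1), "nFolds")
    noAuto <- sim$betas[probeChromosome(sim$betas) %in% c("X", "Y"), ]
    expect_error(trainClock(noAuto, lambda = 0.1), "autosomal")
})

test_that("prediction is linear: imputation shifts by weight * (mean - value)", {
    bs <- makeClockFixture(nSamples = 30)
    model <- trainClock(bs, lambda = 1e-4, seed = 1)
    w <- clockWeights(model)
    expect_gt(length(w), 0)
    target <- names(w)[1]
    b <- betaValues(bs)
    p0 <- predictAge(model, bs)
    bMiss <- b
    bMiss[target, 1] <- NA
    bsMiss <- BetaSet(bMiss,
                      as.data.frame(SummarizedExperiment::colData(bs)),
                      data.frame(probe_id = rownames(b),
                                 chrom = probeChromosome(bs),
                                 probe_class = "cg"))
    p1 <- predictAge(model, bsMiss)
    mu <- model@featureMeans[match(target, clockFeatures(model))]
    shift <- w[[target]] * (mu - b[target, 1])
    expect_equal(p1$predicted_months[1] - p0$predicted_months[1],
                 unname(shift), tolerance = 1e-10)
    expect_equal(p1$predicted_months[-1], p0$predicted_months[-1])
})

test_that("prediction is invariant to sample and probe order and flags missing", {
    bs <- makeClockFixture(nSamples = 20)
    model <- trainClock(bs, lambda = 1e-4, seed = 1)
    perm <- bs[sample(nrow(bs)), sample(ncol(bs))]
    p0 <- predictAge(model, bs)
    p1 <- predictAge(model, perm)
    expect_equal(p1[rownames(p0), "predicted_months"],
                 p0$predicted_months)
    # dropping most model features flags every sample
    few <- bs[setdiff(rownames(bs), clockFeatures(model)), ]
    expect_warning(p2 <- predictAge(model, few), "missing")
    expect_true(all(p2$high_missing))
})

test_that("zero-weight model with a fixed intercept predicts that intercept", {
    model <- new("ClockModel", probes = character(0), weights = numeric(0),
                 intercept = 6, featureMeans = numeric(0), alpha = 0.5,
                 lambda = 1, nFolds = 10L, seed = 1L, nTrain = 0L)
    bs <- makeClockFixture(nSamples = 10)
    pred <- predictAge(model, bs)
    expect_true(all(pred$predicted_months == 6))
})

test_that("residual comparison: medians, shifts and the rank-sum oracle", {
    mkPred <- function(fieldRes, labRes) {
        n <- length(fieldRes) + length(labRes)
        S4Vectors::DataFrame(
            sample_id = paste0("s", seq_len(n)),
            predicted_months = 0, age_months = 0,
            residual_months = c(fieldRes, labRes),
            frac_features_missing = 0, high_missing = FALSE,
            environment = rep(c("field", "lab"),
                              c(length(fieldRes), length(labRes))))
    }
    res <- c(-1, 0, 0.5, 2, 3)
    same <- compareResiduals(mkPred(res, res))
    expect_equal(same$median_difference, 0)
    expect_gt(same$p, 0.9)
    set.seed(2)
    labRes <- rnorm(20)
    shifted <- compareResiduals(mkPred(labRes + 1, labRes))
    expect_equal(shifted$median_difference, 1, tolerance = 1e-12)
    # exact permutation oracle at small n (distinct values, no ties)
    set.seed(6)
    x <- rnorm(7)
    y <- rnorm(8) + 0.8
    got <- compareResiduals(mkPred(x, y))
    expect_equal(got$p, rankSumPermutationOracle(x, y), tolerance = 1e-10)
    expect_error(compareResiduals(mkPred(1:2, 1:5)), ">= 3 samples")
})

test_that("clock models survive a serialize/deserialize round trip", {
    bs <- makeClockFixture(nSamples = 30)
    model <- trainClock(bs, lambda = 1e-3, seed = 7)
    path <- tempfile(fileext = ".tsv")
    writeClockModel(model, path)
    back <- readClockModel(path)
    expect_equal(clockFeatures(back), clockFeatures(model))
    expect_equal(clockWeights(back), clockWeights(model), tolerance = 1e-12)
    expect_equal(back@intercept, model@intercept, tolerance = 1e-12)
    p1 <- predictAge(model, bs)
    p2 <- predictAge(back, bs)
    expect_equal(p2$predicted_months, p1$predicted_months,
                 tolerance = 1e-10)
})

test_that("a lab-trained clock reads accelerated field samples as older", {
    sim <- simulateCohorts(SimConfig(nProbes = 400, nLab = 30, nField = 30,
                                     rateRatioHyper = 2, rateRatioHypo = 2,
                                     classFractions = c(hyper = 0.3,
                                                        hypo = 0.2,
                                                        null = 0.48,
                                                        sex_linked = 0.02),
                                     missingRate = 0, seed = 87))
    lab <- sim$betas[, sampleEnvironment(sim$betas) == "lab"]
    model <- trainClock(lab, nFolds = 5, seed = 3)
    pred <- predictAge(model, sim$betas)
    cmp <- compareResiduals(pred)
    expect_gt(cmp$median_field, cmp$median_lab)
})
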