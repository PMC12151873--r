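makeFit <- function(probes, slope, q, environment = "lab") {
    res <- S4Vectors::DataFrame(
        probe_id = probes, n_used = 20L, filtered = FALSE,
        slope_per_year = slope, slope_se = 0.01,
        p_age = q, q_age = q, sex_coef = 0, p_sex = 1, q_sex = 1,
        row.names = probes)
    new("SiteWiseFit", results = res, modelEnvironment = environment,
        nSamples = 20L, maxMissing = 0.2)
}

test_that("site categorization implements the sign/threshold mapping", {
    probes <- paste0("p", 1:6)
    lab <- makeFit(probes, slope = c(0.1, -0.1, 0.5, 0.1, -0.2, 0.1),
                   q = c(1e-5, 1e-5, 0.5, 1e-5, 1e-5, 0.02))
    field <- makeFit(probes, slope = c(0.2, -0.05, -0.3, -0.1, 0.3, 0.1),
                     q = c(1e-5, 1e-5, 1e-5, 1e-5, 1e-5, 0.02), "field")
    cats <- categorizeSites(lab, field, qThresh = 0.01)
    expect_equal(as.character(cats$category),
                 c("joint_hyper", "joint_hypo", "field_only_sig",
                   "field_down_lab_up", "field_up_lab_down",
                   "not_significant"))
    # threshold is strict: q exactly at the cutoff is not significant
    atCut <- categorizeSites(makeFit("p", 0.1, 0.01),
                             makeFit("p", 0.1, 0.01, "field"))
    expect_equal(as.character(atCut$category), "not_significant")
    # partition property
    expect_equal(sum(table(cats$category)), 6L)
    expect_error(categorizeSites(lab, makeFit(rev(probes), 1:6 / 10,
                                              rep(0.5, 6), "field")),
                 "probe universe")
})

test_that("octant assignment matches the arctangent oracle everywhere", {
    expect_equal(octantOf(1, 2), 2L)      # 63.4 degrees
    expect_equal(octantOf(-1, -0.5), 5L)  # 206.6 degrees
    expect_equal(octantOf(1, 1), 2L)      # 45-degree boundary, half-open
    set.seed(12)
    n <- 10000
    lab <- stats::rnorm(n)
    field <- stats::rnorm(n)
    # force axis-aligned, boundary and origin cases into the sample
    lab[1:8] <- c(1, 0, -1, 0, 2, -2, 2, 0)
    field[1:8] <- c(0, 1, 0, -1, 2, 2, -2, 0)
    expect_identical(octantOf(lab, field), octantOracle(lab, field))
})

test_that("octant summary counts, percentages and masks behave", {
    lab <- c(1, 1, -1, -1, 0.5)
    field <- c(2, 0.2, -2, 0.1, 1)
    s <- octantSummary(lab, field)
    expect_equal(sum(s$count), 5)
    expect_equal(sum(s$percent), 100)
    expect_equal(attr(s, "n_total"), 5)
    s2 <- octantSummary(lab, field, mask = 1:2)
    expect_equal(sum(s2$count), 2)
    expect_error(octantSummary(lab, field, mask = integer(0)), "empty mask")
    expect_error(octantSummary(c(1, NA), c(1, 1)), "finite")
})

test_that("zero-intercept ratio equals the closed form and is scale-equivariant", {
    expect_equal(zeroInterceptRatio(c(1, 2), c(2, 2))@ratio, 1.2)
    x <- c(0.01, 0.03, 0.05, 0.1)
    rr <- zeroInterceptRatio(x, 2 * x)
    expect_equal(rr@ratio, 2)
    expect_equal(pctFaster(rr), 100)
    set.seed(3)
    y <- 2 * x + rnorm(4, 0, 0.01)
    r1 <- zeroInterceptRatio(x, y)
    r3 <- zeroInterceptRatio(x, 3 * y)
    expect_equal(r3@ratio, 3 * r1@ratio)
    expect_equal(sum(x * y) / sum(x^2), r1@ratio)
    expect_true(r1@ciLow <= r1@ratio && r1@ratio <= r1@ciHigh)
    expect_error(zeroInterceptRatio(c(0, 0), c(1, 2)), "undefined ratio")
    expect_error(zeroInterceptRatio(1, 2), ">= 2 sites")
})

test_that("normal and bootstrap intervals agree on well-behaved data", {
    set.seed(8)
    x <- runif(300, 0.02, 0.2)
    y <- 1.5 * x + rnorm(300, 0, 0.02)
    rn <- zeroInterceptRatio(x, y)
    set.seed(9)
    rb <- zeroInterceptRatio(x, y, ciMethod = "bootstrap", nBoot = 4000)
    expect_equal(rb@ratio, rn@ratio)
    expect_equal(rb@ciLow, rn@ciLow, tolerance = 0.02)
    expect_equal(rb@ciHigh, rn@ciHigh, tolerance = 0.02)
})

test_that("Spearman concordance matches a rank-then-Pearson oracle", {
    expect_equal(rateConcordance(1:10, (1:10)^2)$rho, 1)
    expect_equal(rateConcordance(1:10, -(1:10))$rho, -1)
    set.seed(4)
    x <- sample(1:50, 200, replace = TRUE) / 10  # ties present
    y <- x + rnorm(200)
    got <- rateConcordance(x, y)
    expect_equal(got$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(got$n, 200)
    expect_error(rateConcordance(rep(1, 5), 1:5), "constant")
})

test_that("interaction direction counting follows the faster-in-field convention", {
    probes <- paste0("p", 1:7)
    lab <- makeFit(probes, slope = c(0.1, 0.1, 0.1, 0.1, 0.1, -0.1, -0.1),
                   q = rep(1e-6, 7))
    field <- makeFit(probes, slope = c(0.2, 0.2, 0.2, 0.2, 0.2, -0.2, -0.05),
                     q = rep(1e-6, 7), "field")
    cats <- categorizeSites(lab, field)
    ri <- S4Vectors::DataFrame(
        probe_id = probes, n_used = 20L, filtered = FALSE,
        age_coef = 0.1,
        age_env_coef = c(0.1, 0.1, 0.1, -0.1, 0.1, -0.1, 0.05),
        interaction_se = 0.01,
        p_int = c(1e-6, 1e-6, 1e-6, 1e-6, 0.5, 1e-6, 1e-6),
        q_int = c(1e-6, 1e-6, 1e-6, 1e-6, 0.5, 1e-6, 1e-6),
        row.names = probes)
    inter <- new("InteractionFit", results = ri, nSamples = 40L,
                 maxMissing = 0.2, sexAdjusted = TRUE)
    d <- countInteractionDirections(cats, inter, qIntThresh = 0.05)
    hyper <- d[d$category == "joint_hyper", ]
    # 5 joint_hyper sites, 4 interaction-significant, 3 with positive coef
    expect_equal(hyper$n_total, 4)
    expect_equal(hyper$n_faster_field, 3)
    expect_equal(hyper$percent, 75)
    hypo <- d[d$category == "joint_hypo", ]
    # hypo faster-in-field means a *negative* interaction coefficient
    expect_equal(hypo$n_total, 2)
    expect_equal(hypo$n_faster_field, 1)
    # empty-set contract: no significant interactions -> NA percent
    ri2 <- ri
    ri2$q_int <- rep(0.9, 7)
    inter2 <- new("InteractionFit", results = ri2, nSamples = 40L,
                  maxMissing = 0.2, sexAdjusted = TRUE)
    d2 <- countInteractionDirections(cats, inter2)
    expect_equal(d2$n_total, c(0, 0))
    expect_true(all(is.na(d2$percent)))
})

test_that("faster-in-field sign semantics hold on generated data", {
    sim <- simulateCohorts(SimConfig(nProbes = 600, nLab = 20, nField = 20,
                                     rateRatioHyper = 2, rateRatioHypo = 2,
                                     noiseSd = 0.01, missingRate = 0,
                                     seed = 61))
    truth <- sim$truth
    hyper <- truth$class == "hyper"
    hypo <- truth$class == "hypo"
    expect_true(all(truth$slope_field_per_year[hyper] >
                    truth$slope_lab_per_year[hyper]))
    expect_true(all(truth$slope_field_per_year[hypo] <
                    truth$slope_lab_per_year[hypo]))
})
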