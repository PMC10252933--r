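small_cfg <- function(...) {
    syntheticConfig(nGenes = 60, nLines = 40,
                    lineages = c(AML = 10, skin = 10),
                    fracCommonEssential = 0.1, implantsPerLineage = 3,
                    ...)
}

test_that("identical config and seed give bit-identical datasets", {
    a <- simulateScreenDataset(small_cfg(seed = 7))
    b <- simulateScreenDataset(small_cfg(seed = 7))
    expect_identical(as.matrix(a$effects), as.matrix(b$effects))
    expect_identical(as.matrix(a$expression), as.matrix(b$expression))
    expect_identical(a$truth, b$truth)
    c <- simulateScreenDataset(small_cfg(seed = 8))
    expect_false(identical(as.matrix(a$effects), as.matrix(c$effects)))
})

test_that("scores sit at their class means in the vanishing-noise limit", {
    cfg <- small_cfg(noiseSd = 1e-6, seed = 3)
    sim <- simulateScreenDataset(cfg)
    V <- as.matrix(sim$effects)
    truth <- sim$truth
    g <- truth$gene[truth$class == "lineage_specific" &
                    truth$lineage == "AML"][1]
    inLines <- linesOf(sim$lineages, "AML")
    expect_true(all(abs(V[inLines, g] - cfg$effectImplant) < 4e-6))
    expect_true(all(abs(V[setdiff(rownames(V), inLines), g]) < 4e-6))
    common <- truth$gene[truth$class == "common_essential"][1]
    expect_true(all(abs(V[, common] - cfg$effectCommon) < 4e-6))
})

test_that("class means are recovered under noise", {
    sim <- simulateScreenDataset(syntheticConfig(seed = 5))
    V <- as.matrix(sim$effects)
    truth <- sim$truth
    non <- V[, truth$gene[truth$class == "nonessential"]]
    tol <- 4 * 0.3 / sqrt(length(non))
    expect_lt(abs(mean(non)), tol)
    com <- V[, truth$gene[truth$class == "common_essential"]]
    expect_lt(abs(mean(com) + 1), 4 * 0.3 / sqrt(length(com)))
})

test_that("the score-to-probability map hits its anchors and is monotone", {
    expect_equal(scoreToProbability(-0.5), 0.5)
    expect_gt(scoreToProbability(-1), 0.99)
    expect_lt(scoreToProbability(0), 0.01)
    grid <- seq(-2, 1, by = 0.05)
    expect_true(all(diff(scoreToProbability(grid)) < 0))
})

test_that("impossible configs are rejected", {
    expect_error(syntheticConfig(nGenes = 10, lineages = c(A = 5, B = 5),
                                 implantsPerLineage = 5,
                                 fracCommonEssential = 0.5),
                 "more common-essential plus implanted")
    expect_error(syntheticConfig(nLines = 10, lineages = c(A = 20)),
                 "sum to more than")
    expect_error(syntheticConfig(noiseSd = 0), "noiseSd")
})

test_that("RNAi replicate reproduces CRISPR exactly at reliability 1", {
    cfg <- small_cfg(rnaiReliabilityHigh = 1, rnaiReliabilityLow = 1,
                     seed = 9)
    sim <- simulateScreenDataset(cfg)
    rnai <- simulateRnaiReplicate(sim$effects, sim$truth, cfg)
    expect_identical(platform(rnai), "rnai")
    expect_equal(as.matrix(rnai), as.matrix(sim$effects), tolerance = 1e-15)
})

test_that("RNAi cross-platform correlation tracks the reliability", {
    # reliability 0 -> |rho| < 0.1; reliability 0.9 -> rho in [0.8, 0.96],
    # measured on nonessential genes at 200 lines over 20 seeds
    cors0 <- cors9 <- numeric(20)
    for (i in 1:20) {
        cfg <- syntheticConfig(nGenes = 10, nLines = 200,
                               lineages = c(A = 20, B = 20),
                               fracCommonEssential = 0, implantsPerLineage = 0,
                               rnaiReliabilityHigh = 0.9,
                               rnaiReliabilityLow = 0, seed = 100 + i)
        sim <- simulateScreenDataset(cfg)
        rnai <- simulateRnaiReplicate(sim$effects, sim$truth, cfg)
        hi <- sim$truth$gene[sim$truth$accuracy_group == "high"][1]
        lo <- sim$truth$gene[sim$truth$accuracy_group == "low"][1]
        cors9[i] <- cor(as.matrix(sim$effects)[, hi], as.matrix(rnai)[, hi])
        cors0[i] <- cor(as.matrix(sim$effects)[, lo], as.matrix(rnai)[, lo])
    }
    expect_true(all(abs(cors0) < 0.2))
    expect_lt(abs(mean(cors0)), 0.1)
    expect_true(all(cors9 > 0.8 & cors9 < 0.96))
})

test_that("clinical cohorts hit their fold-change-median target", {
    for (i in 1:20) {
        co <- simulateClinicalCohort(fcMedianTarget = 1, seed = 200 + i)
        fc <- median(co$tumor) / median(co$normal)
        expect_gt(fc, 0.8)
        expect_lt(fc, 1.25)
    }
    co <- simulateClinicalCohort(fcMedianTarget = 150, seed = 1)
    fc <- median(co$tumor) / median(co$normal)
    expect_lt(abs(fc - 150) / 150, 0.3)
    z <- simulateClinicalCohort(zeroNormal = TRUE, seed = 1)
    expect_true(all(z$normal == 0))
    expect_error(simulateClinicalCohort(nTumor = 0), "positive")
    expect_error(simulateClinicalCohort(fcMedianTarget = -1), "positive")
})

test_that("survival cohorts respect censoring and size constraints", {
    co <- simulateSurvivalCohort(hrTarget = 1, n = 100, censorRate = 0,
                                 seed = 4)
    expect_true(all(co$event == 1L))
    co2 <- simulateSurvivalCohort(hrTarget = 1, n = 2000, censorRate = 0.4,
                                  seed = 4)
    expect_lt(abs(mean(co2$event == 0L) - 0.4), 0.08)
    expect_error(simulateSurvivalCohort(n = 5), "at least 10")
    expect_error(simulateSurvivalCohort(hrTarget = 0), "positive")
    expect_error(simulateSurvivalCohort(censorRate = 1), "censorRate")
})
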