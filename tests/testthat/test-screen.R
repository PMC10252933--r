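test_that("twoSampleT matches its closed form and the reference routine", {
    # pooled-sd fixture: sd 0.1 in both groups, difference -1
    r <- twoSampleT(c(-1, -0.9, -1.1), c(0, 0.1, -0.1))
    expect_equal(r$t, -sqrt(150), tolerance = 1e-10)
    expect_equal(r$df, 4)
    expect_equal(r$p, 2 * pt(-sqrt(150), 4), tolerance = 1e-12)
    # random draws against the reference implementation, both variants
    set.seed(31)
    for (i in 1:10) {
        a <- rnorm(20)
        b <- rnorm(20, sd = 1.7)
        for (pooled in c(TRUE, FALSE)) {
            mine <- twoSampleT(a, b, pooled = pooled)
            ref <- oracle_t(a, b, pooled = pooled)
            expect_equal(mine$t, ref$t, tolerance = 1e-10)
            expect_equal(mine$p, ref$p, tolerance = 1e-10)
            expect_equal(mine$df, ref$df, tolerance = 1e-8)
        }
    }
})

test_that("twoSampleT degenerate conventions and errors", {
    expect_warning(r <- twoSampleT(c(1, 1, 1), c(1, 1, 1)), "constant")
    expect_identical(r$t, 0)
    expect_identical(r$p, 1)
    r2 <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r2$t, 0)
    expect_equal(r2$p, 1)
    expect_error(twoSampleT(1, c(1, 2)), "at least two")
})

test_that("t is antisymmetric under group swap and location-equivariant", {
    set.seed(32)
    a <- rnorm(12)
    b <- rnorm(15, mean = -0.5)
    expect_equal(twoSampleT(a, b)$t, -twoSampleT(b, a)$t, tolerance = 1e-12)
    shift <- twoSampleT(a + 3.7, b + 3.7)
    expect_equal(shift$t, twoSampleT(a, b)$t, tolerance = 1e-9)
})

test_that("screenLineage reproduces an exhaustive per-gene oracle", {
    set.seed(33)
    m <- make_score_matrix(30, 10, seed = 33, naFrac = 0.05)
    ge <- GeneEffectMatrix(m, "crispr")
    ann <- LineageAnnotation(rownames(m),
                             rep(c("focal", "rest1", "rest2"), each = 10))
    res <- screenLineage(ge, ann, "focal", k = 10)
    inRows <- rownames(m) %in% linesOf(ann, "focal")
    ref <- vapply(colnames(m), function(g) {
        a <- m[inRows, g]
        b <- m[!inRows, g]
        oracle_t(a[!is.na(a)], b[!is.na(b)])$t
    }, numeric(1))
    ord <- names(sort(ref))
    expect_identical(res$gene, ord)
    expect_equal(res$t_statistic, unname(sort(ref)), tolerance = 1e-10)
    expect_identical(res$rank, 1:10)
})

test_that("a uniquely lethal gene ranks first and k limits the output", {
    m <- matrix(0, 30, 8,
                dimnames = list(sprintf("L%02d", 1:30),
                                sprintf("G%d", 1:8)))
    m[, ] <- rep(seq(-0.001, 0.001, length.out = 30), 8)  # tiny spread
    m[1:10, "G5"] <- -1
    ge <- GeneEffectMatrix(m, "crispr")
    ann <- LineageAnnotation(rownames(m), rep(c("A", "B", "C"), each = 10))
    res <- screenLineage(ge, ann, "A", k = 5)
    expect_identical(res$gene[1], "G5")
    expect_identical(nrow(res), 5L)
    expect_true(all(diff(res$t_statistic) >= 0))
})

test_that("equal-t ties break lexicographically by gene label", {
    m <- matrix(rep(c(-1, -1, 0, 0), 3), 4, 3,
                dimnames = list(c("a", "b", "c", "d"),
                                c("zeta", "alpha", "mid")))
    ge <- GeneEffectMatrix(m, "crispr")
    ann <- LineageAnnotation(c("a", "b", "c", "d"), c("X", "X", "Y", "Y"))
    res <- screenLineage(ge, ann, "X", k = 3)
    expect_identical(res$gene, c("alpha", "mid", "zeta"))
})

test_that("screening is invariant to gene column order", {
    m <- make_score_matrix(20, 12, seed = 34)
    ann <- LineageAnnotation(rownames(m), rep(c("A", "B"), each = 10))
    r1 <- screenLineage(GeneEffectMatrix(m, "crispr"), ann, "A", k = 12)
    perm <- sample(ncol(m))
    r2 <- screenLineage(GeneEffectMatrix(m[, perm], "crispr"), ann, "A",
                        k = 12)
    expect_identical(r1$gene, r2$gene)
    expect_equal(r1$t_statistic, r2$t_statistic, tolerance = 1e-12)
})

test_that("screenAll screens every lineage independently and reports failures", {
    sim <- simulateScreenDataset(syntheticConfig(
        nGenes = 80, nLines = 41, lineages = c(A = 10, B = 10, C = 20),
        fracCommonEssential = 0, implantsPerLineage = 2, seed = 2))
    expect_warning(st <- screenAll(sim$effects, sim$lineages, k = 5),
                   "omitted")
    # 'other' has a single line and must be dropped with a warning
    expect_false("other" %in% names(st))
    expect_identical(sort(names(st)), c("A", "B", "C"))
    expect_true(all(vapply(st, nrow, integer(1)) == 5L))
    flat <- as.data.frame(st)
    expect_identical(nrow(flat), 15L)
    # single-lineage annotation: the unannotated matrix lines are the rest
    ann1 <- LineageAnnotation(lineIDs(sim$effects)[1:10], "solo")
    st1 <- screenAll(sim$effects, ann1, k = 3)
    expect_identical(names(st1), "solo")
    expect_identical(st1$solo$n_out[1], 31L)
})

test_that("screen skips undersized genes instead of failing", {
    m <- make_score_matrix(10, 3, seed = 35)
    m[1:4, 2] <- NA
    ann <- LineageAnnotation(rownames(m), rep(c("A", "B"), each = 5))
    m[5, 2] <- NA  # gene 2 now has no present value in the focal group
    res <- screenLineage(GeneEffectMatrix(m, "crispr"), ann, "A", k = 3)
    expect_identical(attr(res, "skipped"), colnames(m)[2])
    expect_identical(nrow(res), 2L)
})

test_that("recovery power is monotone in effect size, lineage size and noise", {
    recovery <- function(effect, size, noise, seeds = 1:4) {
        mean(vapply(seeds, function(s) {
            cfg <- syntheticConfig(nGenes = 200, nLines = 100,
                                   lineages = setNames(rep(size, 2),
                                                       c("A", "B")),
                                   fracCommonEssential = 0,
                                   implantsPerLineage = 5,
                                   effectImplant = effect, noiseSd = noise,
                                   seed = 700 + s)
            sim <- simulateScreenDataset(cfg)
            st <- screenAll(sim$effects, sim$lineages, k = 5)
            imp <- sim$truth[sim$truth$class == "lineage_specific", ]
            mean(vapply(c("A", "B"), function(l)
                mean(imp$gene[imp$lineage == l] %in% st[[l]]$gene),
                numeric(1)))
        }, numeric(1)))
    }
    byEffect <- c(recovery(-0.1, 10, 0.6), recovery(-0.5, 10, 0.6),
                  recovery(-1.5, 10, 0.6))
    expect_true(all(diff(byEffect) >= 0))
    bySize <- c(recovery(-0.5, 4, 0.6), recovery(-0.5, 12, 0.6),
                recovery(-0.5, 30, 0.6))
    expect_true(all(diff(bySize) >= 0))
    byNoise <- c(recovery(-0.5, 10, 0.25), recovery(-0.5, 10, 0.8),
                 recovery(-0.5, 10, 2.5))
    expect_true(all(diff(byNoise) <= 0))
})

test_that("dependency calls use a strict > threshold and keep NAs", {
    p <- matrix(c(1, 0, 0.5, NA), 2, 2,
                dimnames = list(c("L1", "L2"), c("G1", "G2")))
    calls <- callDependency(DependencyProbabilityMatrix(p))
    expect_identical(calls[1, 1], TRUE)
    expect_identical(calls[2, 1], FALSE)
    expect_identical(calls[1, 2], FALSE)  # exactly 0.5 is not a call
    expect_true(is.na(calls[2, 2]))
    expect_error(callDependency(DependencyProbabilityMatrix(p), 1.5),
                 "threshold")
})

test_that("a common-essential gene is called dependent in nearly all lines", {
    sim <- simulateScreenDataset(syntheticConfig(seed = 6))
    calls <- callDependency(sim$probability)
    common <- sim$truth$gene[sim$truth$class == "common_essential"]
    expect_gte(mean(calls[, common]), 0.95)
})
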