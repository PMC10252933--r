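test_that("Fisher 2x2 matches hypergeometric enumeration", {
    expect_equal(fisherExact2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
    expect_equal(fisherExact2x2(0, 10, 0, 90), 1)  # degenerate margin
    set.seed(71)
    for (i in 1:25) {
        tab <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
        mine <- fisherExact2x2(tab[1], tab[2], tab[3], tab[4])
        ref <- oracle_fisher(tab[1], tab[2], tab[3], tab[4])
        expect_equal(mine, ref, tolerance = 1e-10)
    }
    expect_error(fisherExact2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher p is symmetric under transposing the 2x2 roles", {
    set.seed(72)
    for (i in 1:10) {
        tab <- sample(0:15, 4, replace = TRUE)
        expect_equal(fisherExact2x2(tab[1], tab[2], tab[3], tab[4]),
                     fisherExact2x2(tab[1], tab[3], tab[2], tab[4]),
                     tolerance = 1e-12)
    }
})

test_that("BH adjustment matches a literal step-up and is well-behaved", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
    expect_equal(bhFdr(0.37), 0.37)
    set.seed(73)
    for (i in 1:10) {
        p <- runif(sample(2:40, 1))
        adj <- bhFdr(p)
        expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
        ord <- order(p)
        expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone in sorted order
        expect_true(all(adj <= 1 & adj >= p - 1e-15))
    }
    # idempotent on already-adjusted uniform (all-equal) inputs
    expect_equal(bhFdr(bhFdr(rep(0.07, 6))), rep(0.07, 6))
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("category enrichment computes fold enrichment and FDR", {
    # study entirely inside one category covering 10% of the background
    bg <- sprintf("G%03d", 1:200)
    ann <- AnnotationTable(gene = c(bg[1:20], bg[21:60]),
                           category = c(rep("inCat", 20), rep("big", 40)),
                           background = bg)
    res <- categoryEnrichment(bg[1:10], ann)
    row <- res[res$category == "inCat", ]
    expect_equal(row$fold_enrichment, 10)
    expect_equal(row$expected, 1)
    expect_equal(row$p_raw,
                 oracle_fisher(10, 0, 10, 180), tolerance = 1e-10)
    expect_equal(res$fdr, bhFdr(res$p_raw))
    # the reported-semantics check: 52 of 126 hits vs expected 6.83
    bg2 <- sprintf("H%04d", 1:2000)
    inCat <- 109L  # background category size => expected ~6.87 for 126 study
    ann2 <- AnnotationTable(gene = bg2[1:inCat], category = "dna_binding",
                            background = bg2)
    study <- c(bg2[1:52], bg2[(inCat + 1):(inCat + 74)])  # 52 in, 74 out
    res2 <- categoryEnrichment(study, ann2)
    expect_equal(res2$n_study[1], 52L)
    expect_equal(res2$fold_enrichment[1],
                 52 / (126 * inCat / 2000), tolerance = 1e-12)
    expect_lt(res2$p_raw[1], 1e-20)
})

test_that("uniform draws from the background are unenriched on average", {
    bg <- sprintf("G%04d", 1:1000)
    ann <- AnnotationTable(gene = bg[1:500], category = "half",
                           background = bg)
    folds <- vapply(1:20, function(i) {
        set.seed(800 + i)
        study <- sample(bg, 100)
        categoryEnrichment(study, ann)$fold_enrichment[1]
    }, numeric(1))
    expect_gt(mean(folds), 0.8)
    expect_lt(mean(folds), 1.25)
})

test_that("BH keeps the null category discovery rate controlled", {
    bg <- sprintf("G%04d", 1:500)
    set.seed(74)
    cats <- paste0("C", 1:20)
    annPairs <- data.frame(gene = sample(bg, 600, replace = TRUE),
                           category = sample(cats, 600, replace = TRUE))
    annPairs <- unique(annPairs)
    ann <- AnnotationTable(annPairs$gene, annPairs$category, background = bg)
    hits <- vapply(1:50, function(i) {
        study <- sample(bg, 40)
        mean(categoryEnrichment(study, ann)$fdr < 0.05)
    }, numeric(1))
    expect_lte(mean(hits), 0.05 + 0.02)
})

test_that("study genes outside the background are dropped with a warning", {
    ann <- AnnotationTable(c("A", "B"), c("c1", "c1"),
                           background = c("A", "B", "C"))
    expect_warning(res <- categoryEnrichment(c("A", "ZZZ"), ann),
                   "outside the background")
    expect_identical(res$n_study_total[1], 1L)
    expect_error(categoryEnrichment(character(0), ann), "empty")
})

test_that("motif-class representation reports both percentage views", {
    # 18 study proteins in a class of 409 carriers -> ~4.4% of the class
    carriers <- sprintf("TF%03d", 1:409)
    others <- sprintf("ZF%03d", 1:100)
    ann <- AnnotationTable(gene = c(carriers, others),
                           category = c(rep("HTH", 409), rep("C2H2", 100)))
    study <- c(carriers[1:18], sprintf("XX%d", 1:22))  # 40 study genes
    res <- motifClassRepresentation(study, ann)
    hth <- res[res$motif_class == "HTH", ]
    expect_identical(hth$n_study_in_class, 18L)
    expect_equal(hth$pct_of_class, 100 * 18 / 409, tolerance = 1e-12)
    expect_equal(hth$pct_of_class, 4.4, tolerance = 0.02)
    expect_equal(hth$pct_of_study, 45)
    expect_identical(attr(res, "classes_hit"), 1L)
    expect_identical(attr(res, "classes_total"), 2L)
    # fully enumerable two-class fixture
    ann2 <- AnnotationTable(gene = c("a", "b", "c", "b"),
                            category = c("m1", "m1", "m2", "m2"))
    res2 <- motifClassRepresentation(c("a", "b"), ann2)
    expect_identical(res2$n_study_in_class[res2$motif_class == "m1"], 2L)
    expect_identical(res2$n_study_in_class[res2$motif_class == "m2"], 1L)
    expect_identical(attr(res2, "classes_hit"), 2L)
    # no study gene annotated -> zero classes hit
    res3 <- motifClassRepresentation(c("q1", "q2"), ann2)
    expect_identical(attr(res3, "classes_hit"), 0L)
})
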