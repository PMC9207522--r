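test_that("low-count filter applies the strict row-sum rule", {
    cts <- rbind(g_sum5 = c(1, 1, 1, 1, 1, 0),
                 g_sum6 = c(1, 1, 1, 1, 1, 1),
                 g_zero = c(0, 0, 0, 0, 0, 0),
                 g_big = c(10, 10, 10, 10, 10, 10))
    colnames(cts) <- paste0("s", 1:6)
    se <- StageExperiment(cts, rep(c("A", "B"), each = 3))
    kept <- rownames(filterLowCountGenes(se))
    expect_identical(kept, c("g_sum6", "g_big"))
})

test_that("median-of-ratios size factors match hand computations", {
    # two identical samples -> factors (1, 1)
    cts <- matrix(c(5, 5, 9, 9, 20, 20), nrow = 3, byrow = TRUE)
    se <- make_se(cts, c("A", "B"))
    expect_equal(unname(sizeFactors(estimateSizeFactors(se))), c(1, 1))

    # sample B = 2 x sample A exactly -> (1/sqrt(2), sqrt(2))
    cts <- matrix(c(4, 8, 10, 20, 7, 14), nrow = 3, byrow = TRUE)
    se <- make_se(cts, c("A", "B"))
    expect_equal(unname(sizeFactors(estimateSizeFactors(se))),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    # genes containing any zero are excluded from the reference set
    cts <- matrix(c(0, 0, 2, 2), nrow = 2, byrow = TRUE)
    se <- make_se(cts, c("A", "B"))
    expect_equal(unname(sizeFactors(estimateSizeFactors(se))), c(1, 1))

    # no all-positive gene -> informative error
    cts <- matrix(c(0, 1, 1, 0), nrow = 2, byrow = TRUE)
    se <- make_se(cts, c("A", "B"))
    expect_error(estimateSizeFactors(se), "no gene has all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(42)
    cts <- matrix(rnbinom(600, mu = 50, size = 10) + 1L, nrow = 100)
    se <- make_se(cts, rep(c("A", "B", "C"), each = 2))
    mine <- unname(sizeFactors(estimateSizeFactors(se)))
    ref <- unname(DESeq2::estimateSizeFactorsForMatrix(cts))
    expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("size factors are equivariant under column scaling", {
    set.seed(7)
    cts <- matrix(rpois(200, 60) + 1L, nrow = 40)
    se <- make_se(cts, c("A", "A", "B", "B", "B"))
    sf0 <- sizeFactors(estimateSizeFactors(se))
    # size factors are defined up to a common scale: scaling sample 3's
    # counts by c scales sf_3 by c relative to every other sample
    for (c_mult in c(2, 5)) {
        cts2 <- cts
        cts2[, 3] <- cts2[, 3] * c_mult
        sf2 <- sizeFactors(estimateSizeFactors(
            make_se(cts2, c("A", "A", "B", "B", "B"))))
        expect_equal(unname((sf2[3] / sf2[1]) / (sf0[3] / sf0[1])),
                     c_mult, tolerance = 1e-10)
    }
})

test_that("normalization divides by size factors; baseMean is its row mean", {
    se <- estimateSizeFactors(tiny_se())
    nm <- normalizeCounts(se)
    expect_equal(nm, sweep(rawCounts(se), 2, sizeFactors(se), "/"))
    expect_equal(baseMeans(se), rowMeans(nm))
    # sf all 1 -> identity
    se1 <- tiny_se()
    SummarizedExperiment::colData(se1)$sizeFactor <- rep(1, 4)
    expect_equal(normalizeCounts(se1), rawCounts(se1) + 0)
})

test_that("gene-wise MoM dispersion is consistent and floors correctly", {
    # NB alpha = 0.2, 10 replicates/stage: median within 25%
    set.seed(31)
    n <- 10000
    cts <- matrix(rnbinom(n * 20, mu = 100, size = 1 / 0.2), nrow = n)
    se <- make_se(cts, rep(c("A", "B"), each = 10))
    SummarizedExperiment::colData(se)$sizeFactor <- rep(1, 20)
    a <- estimateDispersions(se, method = "genewise")
    expect_lt(abs(median(a) - 0.2) / 0.2, 0.25)

    # Poisson data: median at the floor (within 2x)
    set.seed(32)
    ctsp <- matrix(rpois(n * 20, 100), nrow = n)
    sep <- make_se(ctsp, rep(c("A", "B"), each = 10))
    SummarizedExperiment::colData(sep)$sizeFactor <- rep(1, 20)
    ap <- estimateDispersions(sep, method = "genewise")
    expect_lte(median(ap), 2e-8)

    # constant rows sit at the floor; single-replicate design errors
    cc <- matrix(7, 3, 4)
    sec <- make_se(cc, c("A", "A", "B", "B"))
    SummarizedExperiment::colData(sec)$sizeFactor <- rep(1, 4)
    expect_true(all(estimateDispersions(sec, method = "genewise") == 1e-8))
    s1 <- make_se(matrix(1:4, 2), c("A", "B"))
    SummarizedExperiment::colData(s1)$sizeFactor <- c(1, 1)
    expect_error(estimateDispersions(s1, method = "genewise"),
                 "2 replicates")
})

test_that("LRT uses stages-minus-one df and nested likelihood ordering", {
    cfg <- simConfig(nGenes = 60, fractionNull = 0.5, seed = 3)
    d <- simulateDataset(cfg)
    se <- estimateSizeFactors(filterLowCountGenes(d$se))
    disp <- setNames(rep(0.05, nrow(se)), rownames(se))
    res <- nbLRT(se, disp)
    # stat = 2(ll_full - ll_red) >= 0 and chi-square df = 4 for 5 stages
    expect_true(all(res$stat >= 0, na.rm = TRUE))
    expect_equal(res$pvalue,
                 pchisq(res$stat, df = 4, lower.tail = FALSE))
})

test_that("Wald contrast is antisymmetric and finds planted folds", {
    # planted true fold 4 (B/A), mu = 200, alpha = 0.02:
    # median estimated log2FoldChange within [1.8, 2.2]
    set.seed(12)
    n <- 400
    cts <- cbind(matrix(rnbinom(n * 3, mu = 200, size = 50), n),
                 matrix(rnbinom(n * 3, mu = 800, size = 50), n))
    se <- make_se(cts, rep(c("A", "B"), each = 3))
    # size factors fixed at 1: every gene carries the planted fold, so
    # median-of-ratios would (correctly) absorb it as a library effect
    SummarizedExperiment::colData(se)$sizeFactor <- rep(1, 6)
    disp <- setNames(rep(0.02, n), rownames(se))
    ab <- nbWaldTest(se, "A", "B", disp)
    expect_gt(median(ab$log2FoldChange), 1.8)
    expect_lt(median(ab$log2FoldChange), 2.2)
    # swapping A and B negates the fold change, p unchanged
    ba <- nbWaldTest(se, "B", "A", disp)
    expect_equal(ba$log2FoldChange, -ab$log2FoldChange, tolerance = 1e-6)
    expect_equal(ba$pvalue, ab$pvalue, tolerance = 1e-8)
    expect_equal(ab@contrast, "B_vs_A")
    expect_equal(ba@contrast, "A_vs_B")
})

test_that("null Wald contrasts centre on zero fold change", {
    set.seed(13)
    n <- 5000
    cts <- matrix(rnbinom(n * 12, mu = 300, size = 100), n)
    se <- make_se(cts, rep(c("A", "B"), each = 6))
    se <- estimateSizeFactors(se)
    disp <- setNames(rep(0.01, n), rownames(se))
    res <- nbWaldTest(se, "A", "B", disp)
    expect_lt(median(abs(res$log2FoldChange)), 0.1)
})

test_that("a fully separated gene is capped and flagged, not infinite", {
    cts <- rbind(c(0L, 0L, 50L, 60L), c(10L, 12L, 11L, 9L),
                 c(20L, 25L, 19L, 24L))
    se <- make_se(cts, c("A", "A", "B", "B"))
    se <- estimateSizeFactors(se)
    res <- nbWaldTest(se, "A", "B",
                      setNames(rep(0.01, 3), rownames(se)))
    expect_equal(res$log2FoldChange[1], 30)
    expect_equal(res$flag[1], "lfc_capped")
    expect_true(all(is.finite(res$log2FoldChange)))
})

test_that("BH adjustment matches hand computations and its contracts", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(c(0.04, 0.01)), c(0.04, 0.02))
    expect_equal(bhAdjust(0.5), 0.5)
    # NA passthrough: NAs retained, excluded from m
    expect_equal(bhAdjust(c(0.04, NA, 0.01)), c(0.04, NA, 0.02))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
    # permutation invariance and boundedness
    set.seed(4)
    p <- runif(200)
    perm <- sample(200)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    expect_true(all(bhAdjust(p) <= 1))
    # padj is monotone non-decreasing in sorted p order
    adj <- bhAdjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
})
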