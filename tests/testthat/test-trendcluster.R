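test_that("stage means average replicates and respect structure", {
    m <- matrix(c(10, 14, 7, 7, 5,
                  2, 4, 6, 6, 8), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:5)))
    stage <- factor(c("A", "A", "B", "B", "C"), levels = c("A", "B", "C"))
    sm <- stageMeanMatrix(m, stage)
    expect_equal(sm["g1", ], c(A = 12, B = 7, C = 5))
    # single-replicate stage passes through unchanged
    expect_equal(sm[, "C"], m[, 5])
    # permuting replicate columns within stages changes nothing
    sm2 <- stageMeanMatrix(m[, c(2, 1, 4, 3, 5)], stage)
    expect_equal(sm, sm2)
    expect_error(stageMeanMatrix(m, factor(c("A","A","B","B","C"),
                                           levels = c("A","B","C","D"))),
                 "at least one sample")
})

test_that("row z-scoring centres, scales, and drops constant rows", {
    m <- rbind(inc = c(1, 2, 3, 4, 5), const = c(7, 7, 7, 7, 7))
    expect_message(z <- rowZScore(m), "constant")
    expect_equal(rownames(z), "inc")
    expect_equal(attr(z, "dropped"), "const")
    expect_equal(mean(z["inc", ]), 0)
    expect_equal(sqrt(mean(z["inc", ]^2)), 1)  # population SD
    expect_true(all(diff(z["inc", ]) > 0))
    # affine invariance: a + b*x (b > 0) gives identical z-scores
    m2 <- rbind(x = c(3, 1, 4, 1, 5))
    expect_equal(unname(rowZScore(m2)), unname(rowZScore(3 + 2 * m2)))
})

test_that("k = 1 returns the column-mean centroid; bad k errors", {
    set.seed(40)
    z <- matrix(rnorm(50), 10, 5)
    rownames(z) <- paste0("g", 1:10)
    cl <- kmeansTrends(z, k = 1, seed = 1)
    expect_equal(unname(centroids(cl)[1, ]), unname(colMeans(z)),
                 tolerance = 1e-12)
    expect_true(all(clusterAssignments(cl) == 1L))
    expect_error(kmeansTrends(z, k = 11, seed = 1), "exceeds")
    expect_error(kmeansTrends(z, k = 0, seed = 1), ">= 1")
})

test_that("well-separated planted archetypes are recovered exactly", {
    skip_if_not_installed("mclust")
    # between-archetype distance >> within-noise SD: exact recovery
    set.seed(41)
    tmpl <- trendTemplates()
    truth <- sample(1:5, 400, replace = TRUE)
    z <- tmpl[truth, ] + matrix(rnorm(400 * 5, sd = 0.05), 400)
    rownames(z) <- paste0("g", 1:400)
    cl <- kmeansTrends(z, k = 5, seed = 7)
    ari <- mclust::adjustedRandIndex(clusterAssignments(cl), truth)
    expect_equal(ari, 1.0)
    # permuting gene order yields the identical partition after relabel
    perm <- sample(400)
    cl2 <- kmeansTrends(z[perm, ], k = 5, seed = 7)
    expect_equal(clusterAssignments(cl2)[rownames(z)],
                 clusterAssignments(cl))
})

test_that("determinism given seed, and inertia non-increasing in k", {
    set.seed(42)
    z <- matrix(rnorm(600), 120, 5)
    rownames(z) <- paste0("g", 1:120)
    a <- kmeansTrends(z, k = 6, seed = 99)
    b <- kmeansTrends(z, k = 6, seed = 99)
    expect_identical(clusterAssignments(a), clusterAssignments(b))
    expect_identical(centroids(a), centroids(b))
    inert <- vapply(1:12, function(k)
        kmeansTrends(z, k, seed = 5)@totWithinSS, numeric(1))
    expect_true(all(diff(inert) <= 1e-8))
    # cluster ids are ordered by descending size
    sizes <- tabulate(clusterAssignments(a), a@k)
    expect_true(all(diff(sizes) <= 0))
})

test_that("centroids are labelled by the best-correlated template", {
    tmpl <- trendTemplates()
    # a template matches itself at correlation 1
    cl <- new("TrendClusters",
              cluster = setNames(1:5, paste0("g", 1:5)),
              centroids = tmpl, k = 5L, seed = 1L, totWithinSS = 0,
              labels = character(5))
    rownames(cl@centroids) <- 1:5
    out <- matchTrendTemplates(cl)
    m <- attr(out, "matches")
    expect_equal(m$label, rownames(tmpl))
    expect_equal(m$correlation, rep(1, 5), tolerance = 1e-12)

    # a monotone-decreasing centroid must match an early template, never
    # "increasing"
    cen <- rbind(c(2, 1, -0.5, -1, -1.5))
    rownames(cen) <- 1
    cl1 <- new("TrendClusters", cluster = c(g1 = 1L), centroids = cen,
               k = 1L, seed = 1L, totWithinSS = 0, labels = "")
    lab <- attr(matchTrendTemplates(cl1), "matches")$label
    expect_true(lab %in% c("early_only", "early_pair"))

    # all-zero centroid is degenerate -> "custom" with a warning
    cen0 <- matrix(0, 1, 5, dimnames = list(1, NULL))
    cl0 <- new("TrendClusters", cluster = c(g1 = 1L), centroids = cen0,
               k = 1L, seed = 1L, totWithinSS = 0, labels = "")
    expect_warning(out0 <- matchTrendTemplates(cl0), "custom")
    expect_equal(attr(out0, "matches")$label, "custom")

    # non-5-stage centroids cannot be matched
    cen4 <- matrix(rnorm(4), 1, 4, dimnames = list(1, NULL))
    cl4 <- new("TrendClusters", cluster = c(g1 = 1L), centroids = cen4,
               k = 1L, seed = 1L, totWithinSS = 0, labels = "")
    expect_equal(attr(matchTrendTemplates(cl4), "matches")$label,
                 "custom")
})
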