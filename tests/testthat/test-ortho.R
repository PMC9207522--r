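test_that("the orthology partition follows the shared-ortholog definition", {
    tab <- orthologyTable(c("zfa", "zfb", "zfc"),
                          c("H1", "H1", "H2"))
    part <- partitionOrthology(tab)
    expect_equal(unname(part$relation[c("zfa", "zfb")]),
                 rep("one_to_many", 2))
    expect_equal(unname(part$relation["zfc"]), "one_to_one")
    expect_equal(part$n_one_to_one, 1L)
    expect_equal(part$n_one_to_many, 2L)

    empty <- orthologyTable(character(), character())
    pe <- partitionOrthology(empty)
    expect_equal(pe$n_annotated, 0L)
    expect_true(is.na(pe$fraction_one_to_one))
})

test_that("directionality collapse follows the printed rule", {
    map <- orthologyTable(c("zfa", "zfb", "zfc", "zfd", "zfe"),
                          c("H1", "H1", "H2", "H2", NA))
    # same direction -> included with that sign
    deg <- data.frame(gene_id = c("zfa", "zfb"), direction = c(1L, 1L),
                      baseMean = 10, log2FoldChange = 2, padj = 0.01,
                      stringsAsFactors = FALSE)
    col <- directionalityCollapse(deg_set_from_frame(deg), map)
    expect_equal(includedGenes(col)$human_gene, "H1")
    expect_equal(includedGenes(col)$direction, 1L)
    expect_equal(nrow(conflictGenes(col)), 0L)

    # opposite significant change -> omitted, conflict recorded
    deg$direction <- c(1L, -1L)
    deg$log2FoldChange <- c(2, -2)
    col <- directionalityCollapse(deg_set_from_frame(deg), map)
    expect_equal(nrow(includedGenes(col)), 0L)
    expect_equal(conflictGenes(col)$human_gene, "H1")

    # the rule quantifies over DEGs only: a non-significant paralog does
    # not veto its significant partner
    deg1 <- data.frame(gene_id = "zfc", direction = 1L, baseMean = 10,
                       log2FoldChange = 2, padj = 0.01,
                       stringsAsFactors = FALSE)
    col <- directionalityCollapse(deg_set_from_frame(deg1), map)
    expect_equal(includedGenes(col)$human_gene, "H2")
    expect_equal(includedGenes(col)$direction, 1L)

    # unannotated DEGs become unresolved records
    dega <- data.frame(gene_id = "zfe", direction = -1L, baseMean = 10,
                       log2FoldChange = -2, padj = 0.01,
                       stringsAsFactors = FALSE)
    col <- directionalityCollapse(deg_set_from_frame(dega), map)
    expect_equal(unresolvedGenes(col)$zf_gene, "zfe")
    expect_equal(nrow(includedGenes(col)), 0L)

    # unsigned sets are refused
    lrt <- deg1; lrt$direction <- NA_integer_
    expect_error(directionalityCollapse(deg_set_from_frame(lrt), map),
                 "signed")
})

test_that("collapse agrees with brute-force enumeration on random tables", {
    set.seed(50)
    for (i in 1:60) {
        cc <- random_collapse_case(200)
        tab <- orthologyTable(cc$map$zf_gene, cc$map$human_gene)
        col <- directionalityCollapse(deg_set_from_frame(cc$deg), tab)
        oracle <- oracle_collapse(cc$deg, cc$map)
        inc <- includedGenes(col)
        expect_identical(sort(inc$human_gene), oracle$included)
        expect_identical(inc$direction[order(inc$human_gene)],
                         oracle$directions)
        expect_identical(sort(conflictGenes(col)$human_gene),
                         oracle$conflicts)
        expect_identical(sort(unresolvedGenes(col)$zf_gene),
                         oracle$unresolved)
        # conservation: every DEG appears in exactly one bucket
        n_contrib <- sum(inc$n_contributors)
        n_conf <- sum(lengths(strsplit(conflictGenes(col)$zf_genes, ",")))
        expect_equal(n_contrib + n_conf + nrow(unresolvedGenes(col)),
                     nrow(cc$deg))
    }
})

test_that("collapsing a pure 1:1 table is a rename", {
    n <- 40
    map <- orthologyTable(paste0("zf", 1:n), paste0("H", 1:n))
    deg <- data.frame(gene_id = paste0("zf", 1:10),
                      direction = rep(c(1L, -1L), 5), baseMean = 10,
                      log2FoldChange = rep(c(2, -2), 5), padj = 0.01,
                      stringsAsFactors = FALSE)
    col <- directionalityCollapse(deg_set_from_frame(deg), map)
    inc <- includedGenes(col)
    expect_equal(nrow(inc), 10L)
    expect_equal(nrow(conflictGenes(col)), 0L)
    expect_equal(inc$zf_contributors, deg$gene_id[
        match(inc$human_gene, paste0("H", 1:n))])
    expect_equal(inc$direction, deg$direction[
        match(inc$human_gene, paste0("H", 1:n))])
})

test_that("coverage arithmetic reproduces the printed conversion numbers", {
    # printed counts: 9,722 one-to-one and 5,361 one-to-many of 15,122
    # annotated among 25,298 coding genes; 80% directional concordance
    cov <- orthologCoverage(9722, 5361, 15122, 25298, 0.8)
    expect_equal(cov$fraction_one_to_one, 64.3, tolerance = 0.3 / 64.3)
    expect_equal(cov$fraction_one_to_many, 35.4, tolerance = 0.3 / 35.4)
    expect_equal(cov$annotated_fraction, 60, tolerance = 0.3 / 60)
    expect_equal(cov$effective_coverage, 92.6, tolerance = 0.3 / 92.6)
    expect_equal(cov$residual_fraction, 7.4, tolerance = 0.3 / 7.4)
    # full concordance converts every annotated gene
    expect_equal(orthologCoverage(9722, 5361, 15083, NA,
                                  1)$effective_coverage, 100)
})

test_that("measured concordance matches the planted generator parameter", {
    cfg <- simConfig(nGenes = 12000, fractionNull = 0.1,
                     paralogFraction = 0.6, concordance = 0.8,
                     fractionUnannotated = 0.05, seed = 61)
    truth <- generateTruth(cfg)
    tab <- generateOrthology(cfg, truth)
    # collapse the planted-truth DEG set (signed genes only)
    signed <- truth[truth$deg_sign != 0, ]
    deg <- data.frame(gene_id = signed$gene_id,
                      direction = as.integer(signed$deg_sign),
                      baseMean = 10,
                      log2FoldChange = 2 * signed$deg_sign, padj = 0.01,
                      stringsAsFactors = FALSE)
    col <- directionalityCollapse(deg_set_from_frame(deg), tab)
    stats <- coverageStatistics(tab, deg_set_from_frame(deg), col)
    n <- stats$n_multi_deg_groups
    expect_gt(n, 500)
    expect_lt(abs(stats$concordant_fraction / 100 - 0.8),
              3 * sqrt(0.8 * 0.2 / n))
    expect_equal(stats$fraction_one_to_one + stats$fraction_one_to_many,
                 100)
    expect_equal(stats$effective_coverage + stats$residual_fraction, 100)
})
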