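# fixture builders and independent oracles shared across test files

make_se <- function(counts, stage, ...) {
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    StageExperiment(counts, stage, ...)
}

# two stages, duplicates, fixed counts — small deterministic fixture
tiny_se <- function() {
    cts <- matrix(c(10, 12, 20, 24,
                    5, 6, 10, 12,
                    100, 90, 110, 95,
                    0, 1, 0, 2), nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("g", 1:4),
                                  c("A1", "A2", "B1", "B2")))
    StageExperiment(cts, c("A", "A", "B", "B"))
}

# brute-force directionality collapse: exhaustive per-human-gene sign-set
# enumeration, independent of the package implementation
oracle_collapse <- function(deg, mapping) {
    hum <- stats::setNames(mapping$human_gene, mapping$zf_gene)
    h <- ifelse(deg$gene_id %in% mapping$zf_gene,
                hum[deg$gene_id], NA_character_)
    unresolved <- sort(deg$gene_id[is.na(h)])
    included <- character(); inc_dir <- integer(); conflicts <- character()
    for (hg in sort(unique(h[!is.na(h)]))) {
        idx <- which(!is.na(h) & h == hg)
        signs <- unique(deg$direction[idx])
        if (length(signs) == 1L) {
            included <- c(included, hg)
            inc_dir <- c(inc_dir, signs)
        } else conflicts <- c(conflicts, hg)
    }
    list(included = included, directions = inc_dir,
         conflicts = conflicts, unresolved = unresolved)
}

# random small orthology table + signed DEG set for property tests
random_collapse_case <- function(n_max = 200) {
    n <- sample.int(n_max, 1L)
    zf <- paste0("zf", seq_len(n))
    # human group sizes 1-3, with some genes unannotated
    hum_pool <- paste0("H", seq_len(max(1L, ceiling(n / 1.5))))
    hum <- sample(hum_pool, n, replace = TRUE)
    hum[stats::runif(n) < 0.15] <- NA
    map <- data.frame(zf_gene = zf, human_gene = hum,
                      stringsAsFactors = FALSE)
    n_deg <- sample.int(n, 1L)
    ids <- sample(zf, n_deg)
    deg <- data.frame(gene_id = ids,
                      direction = sample(c(-1L, 1L), n_deg,
                                         replace = TRUE),
                      baseMean = stats::runif(n_deg, 10, 100),
                      log2FoldChange = stats::runif(n_deg, -3, 3),
                      padj = stats::runif(n_deg, 0, 0.04),
                      stringsAsFactors = FALSE)
    deg$log2FoldChange <- abs(deg$log2FoldChange) * deg$direction
    list(map = map, deg = deg)
}

deg_set_from_frame <- function(deg, contrast = "B_vs_A") {
    methods::new("DEGSet", genes = deg, contrast = contrast,
                 rule = "fold2_fdr", params = list())
}

# hypergeometric upper-tail by direct enumeration (small instances only)
oracle_hyper_tail <- function(k, K, N, q) {
    js <- k:min(K, q)
    sum(choose(K, js) * choose(N - K, q - js)) / choose(N, q)
}

# a DE results object built directly from a data.frame
make_results <- function(df, contrast = "B_vs_A", testType = "Wald") {
    need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue",
              "padj", "flag")
    for (cc in setdiff(need, colnames(df))) {
        df[[cc]] <- switch(cc, flag = "",
                           lfcSE = 1, stat = 0, pvalue = df$padj,
                           NA_real_)
    }
    if (is.null(df$gene_id)) df$gene_id <- paste0("g", seq_len(nrow(df)))
    methods::new("StageDEResults",
                 S4Vectors::DataFrame(df, row.names = df$gene_id),
                 contrast = contrast, testType = testType)
}
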