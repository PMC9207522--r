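#' baseMean-dependent fold-change threshold
#'
#' The minimal |log2 fold change| required for a gene to be called
#' differentially expressed, as a function of its expression level:
#' 5 / sqrt(baseMean) + 0.6. The threshold is strictly decreasing in
#' baseMean, demanding a higher fold for lowly expressed genes, and tends
#' to 0.6 for highly expressed ones.
#'
#' @param baseMean positive mean of normalized counts.
#' @return the threshold 5 / baseMean^0.5 + 0.6.
#' @examples
#' foldChangeThreshold(25)   # 1.6
#' foldChangeThreshold(100)  # 1.1
#' @export
foldChangeThreshold <- function(baseMean) {
    if (any(baseMean <= 0))
        stop("domain error: baseMean must be > 0")
    5 / sqrt(baseMean) + 0.6
}

deg_frame <- function(res, keep, directed) {
    data.frame(gene_id = res$gene_id[keep],
               direction = if (directed)
                   as.integer(sign(res$log2FoldChange[keep]))
                   else NA_integer_,
               baseMean = res$baseMean[keep],
               log2FoldChange = res$log2FoldChange[keep],
               padj = res$padj[keep],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Call DEGs with the baseMean-dependent filter
#'
#' A gene is a member iff baseMean > \code{basemeanMin} (strict) AND
#' padj < \code{padjCut} (strict) AND |log2FoldChange| exceeds the
#' baseMean-dependent threshold [foldChangeThreshold()] (strict). For LRT
#' results, which carry no fold change, the fold criterion is evaluated on
#' \code{pairwiseLfc} — the largest-magnitude pairwise log2 fold change
#' per gene — when supplied, and skipped with a flag otherwise.
#'
#' @param results a \linkS4class{StageDEResults}.
#' @param padjCut adjusted-p threshold (default 0.05; 0.1 is the
#'   documented alternative).
#' @param basemeanMin minimal expression (default 5).
#' @param pairwiseLfc optional named vector of log2 fold changes for LRT
#'   tables (names = gene ids).
#' @return a \linkS4class{DEGSet}; directions are +1/-1 for Wald results
#'   and NA for LRT membership.
#' @export
callDEGs <- function(results, padjCut = 0.05, basemeanMin = 5,
                     pairwiseLfc = NULL) {
    stopifnot(is(results, "StageDEResults"))
    res <- as.data.frame(results)
    is_lrt <- results@testType == "LRT"
    lfc <- if (is_lrt) {
        if (is.null(pairwiseLfc)) NULL
        else unname(pairwiseLfc[res$gene_id])
    } else res$log2FoldChange
    base_ok <- !is.na(res$padj) & res$baseMean > basemeanMin &
        res$padj < padjCut
    fold_skipped <- is.null(lfc)
    keep <- if (fold_skipped) base_ok
            else base_ok & !is.na(lfc) &
                 abs(lfc) > foldChangeThreshold(pmax(res$baseMean,
                                                     .Machine$double.eps))
    if (is_lrt && !fold_skipped) res$log2FoldChange <- lfc
    out <- new("DEGSet", genes = deg_frame(res, keep, directed = !is_lrt),
               contrast = results@contrast,
               rule = "basemean_dependent",
               params = list(padjCut = padjCut, basemeanMin = basemeanMin,
                             fold_criterion = !fold_skipped))
    validObject(out)
    out
}

#' Call DEGs with the simple fold / FDR rule
#'
#' Membership iff |log2FoldChange| >= log2(\code{foldMin}) (inclusive:
#' "at least" \code{foldMin}-fold) AND padj < \code{fdrCut} (strict).
#'
#' @param results a pairwise \linkS4class{StageDEResults}.
#' @param foldMin minimal fold change (default 2).
#' @param fdrCut FDR threshold (default 0.05).
#' @return a \linkS4class{DEGSet} with rule "fold2_fdr".
#' @export
callDEGsSimple <- function(results, foldMin = 2, fdrCut = 0.05) {
    stopifnot(is(results, "StageDEResults"))
    if (results@testType != "Wald")
        stop("the simple fold rule needs a pairwise (Wald) result table")
    res <- as.data.frame(results)
    keep <- !is.na(res$padj) & !is.na(res$log2FoldChange) &
        abs(res$log2FoldChange) >= log2(foldMin) & res$padj < fdrCut
    out <- new("DEGSet", genes = deg_frame(res, keep, directed = TRUE),
               contrast = results@contrast, rule = "fold2_fdr",
               params = list(foldMin = foldMin, fdrCut = fdrCut))
    validObject(out)
    out
}

#' @describeIn callDEGs member table accessor.
#' @param x a DEGSet.
#' @export
degGenes <- function(x) {
    stopifnot(is(x, "DEGSet"))
    x@genes
}

setMethod("show", "DEGSet", function(object) {
    cat("DEGSet: ", nrow(object@genes), " genes, contrast ",
        object@contrast, ", rule ", object@rule, "\n", sep = "")
    d <- object@genes$direction
    if (!all(is.na(d)))
        cat("  up:", sum(d == 1, na.rm = TRUE),
            " down:", sum(d == -1, na.rm = TRUE), "\n")
})

#' Membership partition over several DEG sets (Venn regions)
#'
#' Counts genes per membership signature across the supplied DEG sets —
#' the numbers behind an Edwards Venn diagram of pairwise contrasts. The
#' all-absent signature is not a region; region counts sum to the size of
#' the union.
#'
#' @param degsets named list of \linkS4class{DEGSet} (or plain character
#'   vectors of gene ids).
#' @return data.frame with one row per non-empty signature: one
#'   logical column per set, plus \code{count}.
#' @export
vennPartition <- function(degsets) {
    if (length(degsets) < 2L)
        stop("need at least 2 DEG sets")
    sets <- lapply(degsets, function(s)
        if (is(s, "DEGSet")) degGenes(s)$gene_id else as.character(s))
    if (is.null(names(sets)))
        names(sets) <- paste0("set", seq_along(sets))
    universe <- unique(unlist(sets))
    memb <- vapply(sets, function(g) universe %in% g,
                   logical(length(universe)))
    memb <- matrix(memb, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
    sig <- apply(memb, 1L, function(b) paste(as.integer(b), collapse = ""))
    tab <- table(sig)
    m <- t(vapply(names(tab),
                  function(s) strsplit(s, "")[[1]] == "1",
                  logical(length(sets))))
    colnames(m) <- names(sets)
    out <- as.data.frame(m, row.names = NULL)
    out$count <- as.integer(tab)
    out
}
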