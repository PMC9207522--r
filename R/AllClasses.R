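#' @importFrom methods setClass setValidity new validObject is slot show
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' StageExperiment: a count matrix with a staged design
#'
#' Extends \linkS4class{SummarizedExperiment} with a single \code{"counts"}
#' assay of non-negative integer raw counts and a \code{stage} factor in
#' \code{colData}. Stage level order is the developmental order (for the
#' canonical oocyte groups: Symbrk < Nuc < MatBb < StageII < StageIII).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [StageExperiment()] for construction, [stageOf()], [stageLevels()]
#' @export
setClass("StageExperiment", contains = "SummarizedExperiment")

setValidity("StageExperiment", function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(is.na(cts)))
            msg <- c(msg, "counts must not contain NA")
        else {
            if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(cts != round(cts))) msg <- c(msg, "counts must be integral")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (!("stage" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain a 'stage' column")
    else {
        st <- colData(object)$stage
        if (!is.factor(st))
            msg <- c(msg, "'stage' must be a factor")
        else {
            if (nlevels(st) < 2)
                msg <- c(msg, "at least 2 stages are required")
            if (any(table(st) < 1) || !all(levels(st) %in% as.character(st)))
                msg <- c(msg, "every stage level needs at least one sample")
            if (anyNA(st))
                msg <- c(msg, "every sample must map to exactly one stage")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Differential-expression result table
#'
#' A \linkS4class{DFrame} with one row per tested gene and columns
#' \code{baseMean}, \code{log2FoldChange}, \code{lfcSE}, \code{stat},
#' \code{pvalue}, \code{padj} and \code{flag}, plus the contrast label
#' (\code{"LRT"} or \code{"B_vs_A"}) and test type carried as slots.
#' For the likelihood-ratio test \code{log2FoldChange}/\code{lfcSE} are NA.
#'
#' @slot contrast single string, e.g. \code{"LRT"} or \code{"StageII_vs_Nuc"}.
#' @slot testType \code{"LRT"} or \code{"Wald"}.
#' @export
setClass("StageDEResults", contains = "DFrame",
    representation(contrast = "character", testType = "character"))

setValidity("StageDEResults", function(object) {
    need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue",
              "padj", "flag")
    msg <- character()
    if (!all(need %in% colnames(object)))
        msg <- c(msg, paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (length(object@contrast) != 1L)
        msg <- c(msg, "contrast must be a single string")
    if (!object@testType %in% c("LRT", "Wald"))
        msg <- c(msg, "testType must be 'LRT' or 'Wald'")
    if ("pvalue" %in% colnames(object)) {
        p <- object$pvalue
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "pvalue outside [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' A called DEG set
#'
#' Genes admitted by one of the significance filters, with the admitting
#' rule recorded. \code{direction} is +1/-1 (sign of log2 fold change) for
#' pairwise contrasts and NA for LRT membership.
#'
#' @slot genes data.frame with columns gene_id, direction, baseMean,
#'   log2FoldChange, padj.
#' @slot contrast contrast label the set was called from.
#' @slot rule filter provenance: "basemean_dependent" or "fold2_fdr".
#' @slot params the thresholds used.
#' @export
setClass("DEGSet", representation(genes = "data.frame",
    contrast = "character", rule = "character", params = "list"))

setValidity("DEGSet", function(object) {
    need <- c("gene_id", "direction", "baseMean", "log2FoldChange", "padj")
    msg <- character()
    if (!all(need %in% colnames(object@genes)))
        msg <- c(msg, "genes table missing required columns")
    else if (anyDuplicated(object@genes$gene_id))
        msg <- c(msg, "duplicate gene ids in DEG set")
    if (length(msg)) msg else TRUE
})

#' Zebrafish-to-human orthology table
#'
#' One row per zebrafish gene; \code{human_gene} is NA for genes without a
#' curated human ortholog. The relation partition (one_to_one / one_to_many /
#' unannotated) is recomputed from the table itself: a zebrafish gene is
#' one_to_many iff at least two zebrafish genes share its human ortholog.
#'
#' @slot mapping data.frame with columns zf_gene, human_gene, relation.
#' @export
setClass("OrthologyTable", representation(mapping = "data.frame"))

setValidity("OrthologyTable", function(object) {
    m <- object@mapping
    msg <- character()
    if (!all(c("zf_gene", "human_gene", "relation") %in% colnames(m)))
        msg <- c(msg, "mapping must have zf_gene, human_gene, relation")
    else {
        if (anyDuplicated(m$zf_gene))
            msg <- c(msg, "duplicate zebrafish gene ids")
        if (!all(m$relation %in% c("one_to_one", "one_to_many", "unannotated")))
            msg <- c(msg, "invalid relation labels")
    }
    if (length(msg)) msg else TRUE
})

#' Human-nomenclature DEG set after the directionality collapse
#'
#' @slot included data.frame human_gene, direction, zf_contributors
#'   (comma-separated), n_contributors.
#' @slot conflicts data.frame human_gene, zf_genes, directions — paralog
#'   groups whose significant members changed in opposite directions,
#'   omitted from the included list.
#' @slot unresolved data.frame zf_gene, direction — DEGs without a curated
#'   human ortholog.
#' @slot contrast the pairwise contrast the DEG set came from.
#' @export
setClass("CollapsedDEGSet", representation(included = "data.frame",
    conflicts = "data.frame", unresolved = "data.frame",
    contrast = "character"))

setValidity("CollapsedDEGSet", function(object) {
    msg <- character()
    if (length(intersect(object@included$human_gene,
                         object@conflicts$human_gene)))
        msg <- c(msg, "a human gene cannot be both included and conflicted")
    if (!all(object@included$direction %in% c(-1, 1)))
        msg <- c(msg, "included directions must be +1/-1")
    if (length(msg)) msg else TRUE
})

#' k-means trend clustering of stage-expression profiles
#'
#' @slot cluster named integer vector gene -> cluster id in 1..k; ids are
#'   relabelled by descending cluster size for stability.
#' @slot centroids k x n_stages matrix of cluster means on the z-scored
#'   stage-mean scale.
#' @slot k number of clusters.
#' @slot seed RNG seed the solution is reproducible from.
#' @slot totWithinSS total within-cluster sum of squares (inertia) of the
#'   best-of-n_init solution.
#' @slot labels optional trend-template label per cluster ("" until matched).
#' @export
setClass("TrendClusters", representation(cluster = "integer",
    centroids = "matrix", k = "integer", seed = "integer",
    totWithinSS = "numeric", labels = "character"))

setValidity("TrendClusters", function(object) {
    msg <- character()
    if (nrow(object@centroids) != object@k)
        msg <- c(msg, "centroids must have k rows")
    if (any(object@cluster < 1L | object@cluster > object@k))
        msg <- c(msg, "cluster ids must lie in 1..k")
    if (is.null(names(object@cluster)))
        msg <- c(msg, "cluster vector must be named by gene")
    if (length(msg)) msg else TRUE
})
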