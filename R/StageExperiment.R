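#' Construct a StageExperiment
#'
#' Bundles a gene x sample raw count matrix with its sample-to-stage design.
#' Stage level order is taken from \code{stageLevels} when given, otherwise
#' from order of first appearance in \code{stage}; when the five canonical
#' oocyte group names are used they are put in developmental order
#' (Symbrk, Nuc, MatBb, StageII, StageIII) automatically.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All entries must be
#'   non-negative integers.
#' @param stage character or factor of length \code{ncol(counts)}, or a
#'   named vector matched to \code{colnames(counts)}.
#' @param stageLevels optional character vector fixing stage order.
#' @return a \linkS4class{StageExperiment}.
#' @examples
#' cts <- matrix(rpois(40, 10), 10, 4,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' se <- StageExperiment(cts, c("A", "A", "B", "B"))
#' stageOf(se)
#' @export
StageExperiment <- function(counts, stage, stageLevels = NULL) {
    counts <- as.matrix(counts)
    if (is.numeric(counts) && !is.integer(counts) &&
        !any(is.na(counts)) && all(counts == round(counts)) &&
        max(counts) <= .Machine$integer.max)
        storage.mode(counts) <- "integer"
    if (!is.null(names(stage))) {
        if (!all(colnames(counts) %in% names(stage)))
            stop("design does not cover all samples in the count matrix: ",
                 paste(setdiff(colnames(counts), names(stage)),
                       collapse = ", "))
        stage <- stage[colnames(counts)]
    }
    if (length(stage) != ncol(counts))
        stop("'stage' must have one entry per sample")
    if (is.null(stageLevels)) {
        stageLevels <- if (is.factor(stage)) levels(stage)
                       else unique(as.character(stage))
        if (setequal(stageLevels, CANONICAL_STAGES))
            stageLevels <- CANONICAL_STAGES
    }
    stage <- factor(as.character(stage), levels = stageLevels)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(stage = stage, row.names = colnames(counts)))
    new("StageExperiment", se)
}

#' The five canonical oocyte stage groups, in developmental order
#' @export
CANONICAL_STAGES <- c("Symbrk", "Nuc", "MatBb", "StageII", "StageIII")

#' @describeIn StageExperiment per-sample stage factor.
#' @param x a StageExperiment.
#' @export
stageOf <- function(x) {
    stopifnot(is(x, "StageExperiment"))
    colData(x)$stage
}

#' @describeIn StageExperiment ordered stage labels.
#' @export
stageLevels <- function(x) levels(stageOf(x))

#' @describeIn StageExperiment raw count matrix accessor.
#' @export
rawCounts <- function(x) {
    stopifnot(is(x, "StageExperiment"))
    assay(x, "counts")
}

setMethod("show", "StageExperiment", function(object) {
    cat("StageExperiment:", nrow(object), "genes x", ncol(object),
        "samples\n")
    tab <- table(stageOf(object))
    cat("stages (", length(tab), "): ",
        paste0(names(tab), " [", tab, "]", collapse = ", "), "\n", sep = "")
    if ("sizeFactor" %in% colnames(colData(object)))
        cat("size factors estimated\n")
})
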