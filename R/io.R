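#' Read a count matrix and its stage design
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column, plus a design TSV with columns \code{sample_id} and \code{stage}.
#' Row and column order are preserved as in the files.
#'
#' @param path count matrix TSV.
#' @param designPath design TSV (sample_id, stage).
#' @param stripVersions drop trailing ".N" Ensembl-style version suffixes
#'   from gene ids (off by default; ids are otherwise opaque strings).
#' @return a \linkS4class{StageExperiment}.
#' @export
readCountMatrix <- function(path, designPath, stripVersions = FALSE) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("count matrix needs a gene-id column plus at least one sample")
    gene_ids <- as.character(tab[[1L]])
    if (stripVersions) gene_ids <- sub("\\.\\d+$", "", gene_ids)
    if (anyDuplicated(gene_ids))
        stop("format error: duplicate gene id(s): ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    cts <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(cts) || any(is.na(cts)))
        stop("format error: non-numeric or missing count values")
    if (any(cts < 0))
        stop("format error: negative count value")
    if (any(cts != round(cts)))
        stop("format error: non-integer count value")
    rownames(cts) <- gene_ids

    design <- utils::read.delim(designPath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    if (!all(c("sample_id", "stage") %in% colnames(design)))
        stop("design file must have columns sample_id, stage")
    if (anyDuplicated(design$sample_id))
        stop("format error: duplicate sample id in design")
    if (!all(design$sample_id %in% colnames(cts)))
        stop("consistency error: design sample(s) absent from counts: ",
             paste(setdiff(design$sample_id, colnames(cts)), collapse = ", "))
    if (!all(colnames(cts) %in% design$sample_id))
        stop("consistency error: count sample(s) absent from design: ",
             paste(setdiff(colnames(cts), design$sample_id), collapse = ", "))
    stage <- stats::setNames(design$stage, design$sample_id)
    StageExperiment(cts, stage,
                    stageLevels = unique(design$stage))
}

#' Write a StageExperiment to counts.tsv + design.tsv
#'
#' @param se a StageExperiment.
#' @param countsPath,designPath output TSV paths.
#' @export
writeCountMatrix <- function(se, countsPath, designPath) {
    cts <- rawCounts(se)
    out <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    des <- data.frame(sample_id = colnames(cts),
                      stage = as.character(stageOf(se)),
                      stringsAsFactors = FALSE)
    utils::write.table(des, designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(countsPath, designPath))
}

#' Read a zebrafish-to-human orthology table
#'
#' TSV with columns \code{zf_gene} and \code{human_gene}; an empty or NA
#' human field marks an unannotated gene (recorded, not dropped). An
#' optional third \code{relation} column is accepted but advisory only:
#' the partition is always recomputed from the table itself.
#'
#' @param path orthology TSV.
#' @return an \linkS4class{OrthologyTable}.
#' @export
readOrthologyTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    if (!all(c("zf_gene", "human_gene") %in% colnames(tab)))
        stop("orthology file must have columns zf_gene, human_gene")
    dup <- unique(tab$zf_gene[duplicated(tab$zf_gene)])
    if (length(dup)) {
        # duplicates are tolerated only when fully redundant
        for (z in dup) {
            h <- unique(tab$human_gene[tab$zf_gene == z])
            if (length(h) > 1L)
                stop("format error: zebrafish gene '", z,
                     "' mapped to conflicting human genes: ",
                     paste(h, collapse = ", "))
        }
        tab <- tab[!duplicated(tab$zf_gene), , drop = FALSE]
    }
    orthologyTable(tab$zf_gene, tab$human_gene)
}

#' Construct an OrthologyTable from vectors
#'
#' @param zfGene character vector of zebrafish gene ids (unique).
#' @param humanGene character vector of human orthologs; NA = unannotated.
#' @return an \linkS4class{OrthologyTable} with the one_to_one /
#'   one_to_many / unannotated partition recomputed.
#' @export
orthologyTable <- function(zfGene, humanGene) {
    zfGene <- as.character(zfGene)
    humanGene <- as.character(humanGene)
    if (anyDuplicated(zfGene))
        stop("format error: duplicate zebrafish gene id(s)")
    m <- data.frame(zf_gene = zfGene, human_gene = humanGene,
                    stringsAsFactors = FALSE)
    shared <- table(m$human_gene[!is.na(m$human_gene)])
    m$relation <- ifelse(is.na(m$human_gene), "unannotated",
                  ifelse(shared[m$human_gene] >= 2L, "one_to_many",
                         "one_to_one"))
    new("OrthologyTable", mapping = m)
}

#' @describeIn orthologyTable mapping data.frame accessor.
#' @param x an OrthologyTable.
#' @export
orthologyMapping <- function(x) {
    stopifnot(is(x, "OrthologyTable"))
    x@mapping
}

#' Write an orthology table to TSV
#' @param x an OrthologyTable.
#' @param path output TSV.
#' @export
writeOrthologyTable <- function(x, path) {
    utils::write.table(orthologyMapping(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then member genes, tab-separated.
#' Duplicate members within a term are dropped; empty terms are rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors; term descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("format error: duplicate term id in GMT")
    desc <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "",
                   "")
    sets <- lapply(fields, function(f) {
        g <- unique(f[-(1:2)])
        g[nzchar(g)]
    })
    if (any(lengths(sets) == 0L))
        stop("format error: empty gene set in GMT")
    names(sets) <- ids
    attr(sets, "description") <- stats::setNames(desc, ids)
    sets
}

fmt_num <- function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write pipeline result tables to a directory
#'
#' Writes one TSV per artifact with deterministic column order and fixed
#' float precision, plus a run-metadata JSON (seed, thresholds, versions).
#' Calling twice with the same inputs produces byte-identical outputs.
#'
#' @param degTable data.frame of called DEGs (possibly empty).
#' @param clusterTable data.frame gene_id, cluster_id, trend_label
#'   (or NULL to skip).
#' @param collapsed a \linkS4class{CollapsedDEGSet} (or NULL to skip).
#' @param outDir output directory, created if needed.
#' @param metadata named list written to run_metadata.json.
#' @return invisibly, the paths written.
#' @export
writeResults <- function(degTable, clusterTable = NULL, collapsed = NULL,
                         outDir, metadata = list()) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("I/O error: cannot create output directory ", outDir)
    paths <- character()
    wt <- function(df, file, num_cols = character()) {
        for (cc in intersect(num_cols, colnames(df)))
            df[[cc]] <- fmt_num(df[[cc]])
        p <- file.path(outDir, file)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        p
    }
    deg_cols <- c("gene_id", "contrast", "direction", "baseMean",
                  "log2FoldChange", "padj", "rule")
    degTable <- degTable[, intersect(deg_cols, colnames(degTable)),
                         drop = FALSE]
    paths <- c(paths, wt(degTable, "degs.tsv",
                         c("baseMean", "log2FoldChange", "padj")))
    if (!is.null(clusterTable))
        paths <- c(paths, wt(clusterTable, "clusters.tsv"))
    if (!is.null(collapsed)) {
        paths <- c(paths, wt(collapsed@included, "collapsed.tsv"))
        paths <- c(paths, wt(collapsed@conflicts, "conflicts.tsv"))
        paths <- c(paths, wt(collapsed@unresolved, "unresolved.tsv"))
    }
    meta <- c(metadata,
              list(package_version = as.character(
                       utils::packageVersion("oostage")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = ".")))
    mp <- file.path(outDir, "run_metadata.json")
    jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(c(paths, mp))
}
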