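#' Pipeline configuration
#'
#' Collects the thresholds and options of the end-to-end analysis. Can
#' also be loaded from a YAML file with [readPipelineConfig()].
#'
#' @param countsPath,designPath,orthologyPath,gmtPath input TSV/GMT paths;
#'   any may be NULL when the corresponding object is passed to
#'   [runPipeline()] directly (orthology/gene sets are optional stages).
#' @param excludeFromPairwise stages left out of the pairwise comparisons
#'   (default "Symbrk": the earliest group stays in the LRT/clustering
#'   path but out of the pairwise analysis).
#' @param minTotal low-count filter threshold (row sum, default 6).
#' @param padjCut adjusted-p threshold (default 0.05).
#' @param basemeanMin minimal baseMean (default 5).
#' @param foldRule "basemean_dependent" (the |lfc| > 5/sqrt(baseMean)+0.6
#'   filter) or "fold2_fdr" (|fold| >= 2 and FDR < 0.05).
#' @param kRepresentative,kFine k-means cluster counts (defaults 5 and 12).
#' @param clusterSeed,nInit k-means seeding (defaults 42, 25).
#' @param fdrCut enrichment FDR threshold (default 0.05).
#' @param outDir output directory (NULL = return objects only).
#' @param seed global pipeline seed recorded in the manifest.
#' @return a validated list of class \code{"oostage_pipeline_config"}.
#' @export
pipelineConfig <- function(countsPath = NULL, designPath = NULL,
                           orthologyPath = NULL, gmtPath = NULL,
                           excludeFromPairwise = "Symbrk",
                           minTotal = 6, padjCut = 0.05, basemeanMin = 5,
                           foldRule = c("basemean_dependent", "fold2_fdr"),
                           kRepresentative = 5, kFine = 12,
                           clusterSeed = 42, nInit = 25, fdrCut = 0.05,
                           outDir = NULL, seed = 1) {
    foldRule <- match.arg(foldRule)
    for (p in c(countsPath, designPath, orthologyPath, gmtPath))
        if (!is.null(p) && !file.exists(p))
            stop("input path does not exist: ", p)
    if (padjCut <= 0 || padjCut > 1 || fdrCut <= 0 || fdrCut > 1)
        stop("thresholds must lie in (0, 1]")
    if (minTotal < 0 || basemeanMin < 0)
        stop("count thresholds must be non-negative")
    structure(list(countsPath = countsPath, designPath = designPath,
                   orthologyPath = orthologyPath, gmtPath = gmtPath,
                   excludeFromPairwise = excludeFromPairwise,
                   minTotal = minTotal, padjCut = padjCut,
                   basemeanMin = basemeanMin, foldRule = foldRule,
                   kRepresentative = kRepresentative, kFine = kFine,
                   clusterSeed = clusterSeed, nInit = nInit,
                   fdrCut = fdrCut, outDir = outDir,
                   seed = as.integer(seed)),
              class = "oostage_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipelineConfig()] arguments.
#' @return an \code{"oostage_pipeline_config"} list.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

#' Run the full stage-resolved analysis
#'
#' Executes: low-count filter, median-of-ratios size factors, dispersion
#' estimation, the across-stage LRT plus all pairwise Wald tests among
#' non-excluded stages, BH adjustment, DEG calling, k-means trend
#' clustering of the LRT-significant genes, the directionality collapse
#' per pairwise contrast, and over-representation analysis of the
#' collapsed sets. Writes TSV artifacts plus a manifest (input checksums,
#' config, seed, per-stage record counts) when \code{outDir} is set.
#' Idempotent given the seed: the manifest and outputs are identical
#' across reruns.
#'
#' @param config a [pipelineConfig()].
#' @param se optional \linkS4class{StageExperiment} (else read from
#'   config paths).
#' @param orthology optional \linkS4class{OrthologyTable}.
#' @param geneSets optional named list of gene sets.
#' @return list: se (filtered, with size factors), dispersions, lrt,
#'   wald (list by contrast), degLRT, degPairwise (list), clusters,
#'   collapsed (list), enrichment (list), manifest.
#' @export
runPipeline <- function(config, se = NULL, orthology = NULL,
                        geneSets = NULL) {
    stopifnot(inherits(config, "oostage_pipeline_config"))
    checksums <- list()
    for (p in c(counts = config$countsPath, design = config$designPath,
                orthology = config$orthologyPath, gmt = config$gmtPath))
        checksums[[p]] <- unname(tools::md5sum(p))
    if (is.null(se)) {
        if (is.null(config$countsPath) || is.null(config$designPath))
            stop("stage 'input': provide a StageExperiment or count/",
                 "design paths")
        se <- readCountMatrix(config$countsPath, config$designPath)
    }
    if (is.null(orthology) && !is.null(config$orthologyPath))
        orthology <- readOrthologyTable(config$orthologyPath)
    if (is.null(geneSets) && !is.null(config$gmtPath))
        geneSets <- readGmt(config$gmtPath)

    n_in <- nrow(se)
    se <- filterLowCountGenes(se, config$minTotal)
    se <- estimateSizeFactors(se)
    counts_log <- list(genes_in = n_in,
                       genes_filtered_out = n_in - nrow(se),
                       genes_tested = nrow(se))
    disp <- estimateDispersions(se)

    lrt <- nbLRT(se, disp)
    stages <- stageLevels(se)
    pw_stages <- setdiff(stages, config$excludeFromPairwise)
    prs <- if (length(pw_stages) >= 2) utils::combn(pw_stages, 2,
                                                    simplify = FALSE)
           else list()
    wald <- list()
    for (pr in prs) {
        res <- nbWaldTest(se, pr[1], pr[2], disp)
        wald[[res@contrast]] <- res
    }

    # largest-magnitude pairwise lfc per gene feeds the LRT fold criterion
    pairwiseLfc <- NULL
    if (length(wald)) {
        lfcs <- vapply(wald, function(w) w$log2FoldChange,
                       numeric(nrow(se)))
        lfcs <- matrix(lfcs, nrow = nrow(se))
        pick <- apply(abs(lfcs), 1L, function(r)
            if (all(is.na(r))) NA_integer_ else which.max(r))
        pairwiseLfc <- stats::setNames(
            lfcs[cbind(seq_len(nrow(se)), pick)], rownames(se))
    }
    degLRT <- callDEGs(lrt, config$padjCut, config$basemeanMin,
                       pairwiseLfc)
    degPW <- lapply(wald, function(w)
        if (config$foldRule == "basemean_dependent")
            callDEGs(w, config$padjCut, config$basemeanMin)
        else callDEGsSimple(w, fdrCut = config$padjCut))

    # trend clustering of the LRT-significant genes over ALL stages
    clusters <- NULL
    lrt_genes <- degGenes(degLRT)$gene_id
    if (length(lrt_genes) >= config$kRepresentative) {
        z <- rowZScore(stageMeanMatrix(
            normalizeCounts(se)[lrt_genes, , drop = FALSE], stageOf(se)))
        clusters <- matchTrendTemplates(
            kmeansTrends(z, config$kRepresentative,
                         seed = config$clusterSeed, nInit = config$nInit))
    }

    collapsed <- list()
    enrichment <- list()
    if (!is.null(orthology)) {
        for (nm in names(degPW)) {
            col <- directionalityCollapse(degPW[[nm]], orthology)
            collapsed[[nm]] <- col
            if (!is.null(geneSets)) {
                bg <- unique(stats::na.omit(
                    orthologyMapping(orthology)$human_gene))
                qry <- includedGenes(col)$human_gene
                if (length(qry))
                    enrichment[[nm]] <- hypergeometricORA(
                        qry, geneSets, bg, config$fdrCut)
            }
        }
    }

    manifest <- list(seed = config$seed,
                     config = unclass(config),
                     input_checksums = checksums,
                     record_counts = c(counts_log,
                         list(n_pairwise_contrasts = length(wald),
                              n_lrt_degs = nrow(degGenes(degLRT)),
                              n_pairwise_degs = vapply(degPW, function(d)
                                  nrow(degGenes(d)), integer(1)))))

    if (!is.null(config$outDir)) {
        deg_rows <- lapply(c(list(degLRT), degPW), function(d) {
            g <- degGenes(d)
            if (nrow(g) == 0) g$contrast <- character() else
                g$contrast <- d@contrast
            g$rule <- rep(d@rule, nrow(g))
            g
        })
        degTable <- do.call(rbind, deg_rows)
        clusterTable <- if (!is.null(clusters))
            data.frame(gene_id = names(clusterAssignments(clusters)),
                       cluster_id = unname(clusterAssignments(clusters)),
                       trend_label = trendLabels(clusters)[
                           clusterAssignments(clusters)],
                       row.names = NULL, stringsAsFactors = FALSE)
            else NULL
        writeResults(degTable, clusterTable,
                     if (length(collapsed)) collapsed[[1L]] else NULL,
                     config$outDir,
                     metadata = manifest["seed"])
        jsonlite::write_json(manifest,
                             file.path(config$outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }

    list(se = se, dispersions = disp, lrt = lrt, wald = wald,
         degLRT = degLRT, degPairwise = degPW, clusters = clusters,
         collapsed = collapsed, enrichment = enrichment,
         manifest = manifest)
}
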