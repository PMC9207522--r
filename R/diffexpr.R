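#' Remove genes with low total raw counts
#'
#' Genes with a sum of raw counts less than \code{minTotal} over all
#' samples are filtered out prior to normalization. The comparison is
#' strict: a row sum equal to \code{minTotal} is retained.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param minTotal minimum row sum to keep a gene (default 6).
#' @return the StageExperiment restricted to retained genes, order kept.
#' @export
filterLowCountGenes <- function(se, minTotal = 6) {
    keep <- rowSums(rawCounts(se)) >= minTotal
    se[keep, ]
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes of
#' count_ij / geometric-mean_i, where the reference set is the genes with
#' no zero count in any sample (so every gene contributes a finite
#' geometric mean).
#'
#' @param se a \linkS4class{StageExperiment}.
#' @return the StageExperiment with a \code{sizeFactor} column added to
#'   \code{colData}.
#' @export
estimateSizeFactors <- function(se) {
    cts <- rawCounts(se)
    ref <- rowSums(cts == 0) == 0L
    if (!any(ref))
        stop("normalization error: no gene has all-positive counts; ",
             "supply size factors manually or relax filtering")
    logc <- log(cts[ref, , drop = FALSE])
    loggeo <- rowMeans(logc)
    # median taken on the log-ratio scale (an even-sized reference set
    # then interpolates geometrically, as the reference implementations do)
    sf <- exp(apply(logc - loggeo, 2L, stats::median))
    colData(se)$sizeFactor <- sf
    se
}

#' @describeIn estimateSizeFactors size factor accessor.
#' @export
sizeFactors <- function(se) {
    sf <- colData(se)$sizeFactor
    if (is.null(sf))
        stop("call estimateSizeFactors() first")
    stats::setNames(sf, colnames(se))
}

#' Size-factor-normalized counts
#'
#' @param se a StageExperiment with size factors estimated.
#' @return real-valued matrix normalized_ij = count_ij / sf_j.
#' @export
normalizeCounts <- function(se) {
    sweep(rawCounts(se), 2L, sizeFactors(se), "/")
}

#' Per-gene mean of normalized counts over all samples
#'
#' @param se a StageExperiment with size factors estimated.
#' @return named numeric vector of baseMean values.
#' @export
baseMeans <- function(se) rowMeans(normalizeCounts(se))

#' Method-of-moments dispersion estimates with a mean trend
#'
#' Gene-wise estimates: per stage with >= 2 replicates,
#' alpha_s = (var_s - mean_s) / mean_s^2 on normalized counts, pooled
#' across stages weighted by residual degrees of freedom and floored.
#' With \code{method = "trend"} (the default) a parametric mean trend
#' alpha(mu) = a0 + a1 / mu is fitted to the gene-wise values and each
#' gene receives the trend value at its baseMean: at duplicate-level
#' replication the gene-wise plug-in is far too noisy for calibrated
#' tests, while the trend borrows strength across thousands of genes.
#' \code{method = "genewise"} returns the raw per-gene estimates (the
#' consistent choice when replication is deep).
#'
#' @param se a StageExperiment with size factors estimated.
#' @param method "trend" (default) or "genewise".
#' @param floor smallest admissible alpha (default 1e-8).
#' @return named numeric vector of per-gene alpha, with
#'   \code{attr(, "method")} recording the estimator; falls back to
#'   gene-wise (with a message) when fewer than 50 informative genes are
#'   available to fit a trend.
#' @export
estimateDispersions <- function(se, method = c("trend", "genewise"),
                                floor = 1e-8) {
    method <- match.arg(method)
    alpha <- genewiseDispersionMoM(se, floor)
    if (method == "genewise") return(alpha)
    bm <- baseMeans(se)
    keep <- alpha > pmax(1e-6, floor)
    if (sum(keep) < 50) {
        message("too few informative genes to fit a dispersion trend; ",
                "using gene-wise estimates")
        return(alpha)
    }
    co <- stats::coef(stats::lm(a ~ x,
        data = data.frame(a = as.numeric(alpha)[keep],
                          x = 1 / bm[keep])))
    fitted <- pmax(floor, co[[1]] + co[[2]] / bm)
    out <- stats::setNames(fitted, names(alpha))
    attr(out, "method") <- "mom_trend"
    attr(out, "trend_coefficients") <- c(a0 = co[[1]], a1 = co[[2]])
    out
}

genewiseDispersionMoM <- function(se, floor = 1e-8) {
    nm <- normalizeCounts(se)
    st <- stageOf(se)
    num <- rep(0, nrow(nm))
    den <- rep(0, nrow(nm))
    for (s in levels(st)) {
        cols <- which(st == s)
        ns <- length(cols)
        if (ns < 2L) next
        m <- rowMeans(nm[, cols, drop = FALSE])
        v <- rowSums((nm[, cols, drop = FALSE] - m)^2) / (ns - 1)
        a <- (v - m) / m^2
        ok <- m > 0
        num[ok] <- num[ok] + (ns - 1) * a[ok]
        den[ok] <- den[ok] + (ns - 1)
    }
    if (all(den == 0))
        stop("dispersion estimation needs >= 2 replicates in >= 1 stage; ",
             "supply alpha explicitly")
    alpha <- ifelse(den > 0, pmax(floor, num / pmax(den, 1)), floor)
    names(alpha) <- rownames(nm)
    attr(alpha, "method") <- "mom_pooled"
    alpha
}

LFC_CAP <- 30

new_de_results <- function(df, contrast, testType) {
    out <- new("StageDEResults", DataFrame(df, row.names = df$gene_id),
               contrast = contrast, testType = testType)
    validObject(out)
    out
}

#' Likelihood-ratio test across all stages
#'
#' Per gene, fits an NB log-link GLM with a stage factor (full model) and
#' an intercept-only model (reduced), both with the gene's fixed
#' dispersion and log size factors as offsets. The statistic
#' 2(ll_full - ll_reduced) is referred to chi-square with
#' (n_stages - 1) degrees of freedom; p-values are BH-adjusted across the
#' converged genes.
#'
#' @param se a StageExperiment with size factors estimated.
#' @param dispersions per-gene alpha; defaults to
#'   [estimateDispersions()].
#' @return a \linkS4class{StageDEResults} with contrast "LRT";
#'   log2FoldChange/lfcSE are NA (the LRT carries no single direction).
#' @export
nbLRT <- function(se, dispersions = NULL) {
    if (is.null(dispersions)) dispersions <- estimateDispersions(se)
    cts <- rawCounts(se)
    st <- stageOf(se)
    off <- log(sizeFactors(se))
    Xf <- stats::model.matrix(~st)
    Xr <- Xf[, 1L, drop = FALSE]
    bm <- baseMeans(se)
    n <- nrow(cts)
    stat <- p <- rep(NA_real_, n)
    flag <- rep("", n)
    df <- nlevels(st) - 1L
    for (i in seq_len(n)) {
        ff <- nbGlmFit(cts[i, ], Xf, off, dispersions[i])
        fr <- nbGlmFit(cts[i, ], Xr, off, dispersions[i])
        if (!ff$converged || !fr$converged) {
            flag[i] <- "not_converged"
            next
        }
        stat[i] <- max(0, 2 * (ff$logLik - fr$logLik))
        p[i] <- stats::pchisq(stat[i], df = df, lower.tail = FALSE)
    }
    res <- data.frame(gene_id = rownames(cts), baseMean = bm,
                      log2FoldChange = NA_real_, lfcSE = NA_real_,
                      stat = stat, pvalue = p, padj = bhAdjust(p),
                      flag = flag, stringsAsFactors = FALSE)
    new_de_results(res, "LRT", "LRT")
}

#' Pairwise Wald test between two stages
#'
#' Per gene, fits an NB GLM on the two stages' samples with the gene's
#' fixed dispersion; \code{log2FoldChange} is the stage-B coefficient on
#' the log2 scale, \code{stat} the coefficient over its standard error,
#' and p two-sided normal. Infinite estimates from fully separated genes
#' (one group all zero) are capped at +/- 30 and flagged. baseMean is the
#' mean of normalized counts over ALL samples, so it is identical across
#' contrasts.
#'
#' @param se a StageExperiment with size factors estimated.
#' @param stageA,stageB stage labels; the contrast is B vs A.
#' @param dispersions per-gene alpha; defaults to
#'   [estimateDispersions()] on the full experiment.
#' @return a \linkS4class{StageDEResults} with contrast "B_vs_A".
#' @export
nbWaldTest <- function(se, stageA, stageB, dispersions = NULL) {
    st <- stageOf(se)
    if (!all(c(stageA, stageB) %in% levels(st)))
        stop("unknown stage label")
    if (is.null(dispersions)) dispersions <- estimateDispersions(se)
    sel <- st %in% c(stageA, stageB)
    cts <- rawCounts(se)[, sel, drop = FALSE]
    grp <- factor(as.character(st[sel]), levels = c(stageA, stageB))
    off <- log(sizeFactors(se))[sel]
    X <- stats::model.matrix(~grp)
    bm <- baseMeans(se)
    n <- nrow(cts)
    lfc <- se_ <- stat <- p <- rep(NA_real_, n)
    flag <- rep("", n)
    for (i in seq_len(n)) {
        fit <- nbGlmFit(cts[i, ], X, off, dispersions[i])
        if (!fit$converged) {
            flag[i] <- "not_converged"
            next
        }
        b <- fit$coefficients[2L] / log(2)
        s <- fit$se[2L] / log(2)
        if (!is.finite(s) || s <= 0) {
            flag[i] <- "not_converged"
            next
        }
        if (abs(b) > LFC_CAP) {
            b <- sign(b) * LFC_CAP
            flag[i] <- "lfc_capped"
        }
        lfc[i] <- b
        se_[i] <- s
        stat[i] <- fit$coefficients[2L] / fit$se[2L]
        p[i] <- 2 * stats::pnorm(-abs(stat[i]))
    }
    res <- data.frame(gene_id = rownames(cts), baseMean = bm,
                      log2FoldChange = lfc, lfcSE = se_, stat = stat,
                      pvalue = p, padj = bhAdjust(p), flag = flag,
                      stringsAsFactors = FALSE)
    new_de_results(res, paste0(stageB, "_vs_", stageA), "Wald")
}

#' Benjamini-Hochberg adjustment without independent filtering
#'
#' Step-up over all tested genes; NA entries (untested or non-converged
#' genes) are passed through and excluded from the number of tests m.
#'
#' @param pvalues numeric vector in [0,1], NAs allowed.
#' @return adjusted p-values aligned to the input order.
#' @export
bhAdjust <- function(pvalues) {
    ok <- !is.na(pvalues)
    if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
        stop("p-values must lie in [0,1]")
    out <- rep(NA_real_, length(pvalues))
    out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
    out
}

setMethod("show", "StageDEResults", function(object) {
    cat("StageDEResults (", object@testType, "), contrast ",
        object@contrast, ": ", nrow(object), " genes\n", sep = "")
    ok <- !is.na(object$padj)
    cat(sum(object$padj < 0.05, na.rm = TRUE), "genes at padj < 0.05 of",
        sum(ok), "tested\n")
    methods::callNextMethod()
})
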