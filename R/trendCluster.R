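#' Replicate-averaged stage expression matrix
#'
#' One column per stage, the arithmetic mean of that stage's replicate
#' columns of the normalized count matrix.
#'
#' @param normMatrix gene x sample normalized matrix (from
#'   [normalizeCounts()]).
#' @param stage per-sample stage factor aligned to the columns.
#' @return gene x stage matrix in stage-level order.
#' @export
stageMeanMatrix <- function(normMatrix, stage) {
    stage <- as.factor(stage)
    if (any(table(stage) == 0) || nlevels(stage) < 1)
        stop("every stage needs at least one sample")
    if (length(stage) != ncol(normMatrix))
        stop("stage vector must match matrix columns")
    out <- vapply(levels(stage), function(s)
        rowMeans(normMatrix[, stage == s, drop = FALSE]),
        numeric(nrow(normMatrix)))
    matrix(out, nrow = nrow(normMatrix),
           dimnames = list(rownames(normMatrix), levels(stage)))
}

#' Row-wise z-scoring of stage profiles
#'
#' Each non-constant row is transformed to mean 0, population SD 1 (the
#' usual heatmap scaling of relative expression across stages). Constant
#' rows carry no trend and are dropped; their ids are reported in
#' \code{attr(, "dropped")} and via a message.
#'
#' @param m gene x stage matrix (>= 2 columns).
#' @return z-scored matrix, possibly with fewer rows.
#' @export
rowZScore <- function(m) {
    if (ncol(m) < 2L)
        stop("need at least 2 stages to z-score a trend")
    mu <- rowMeans(m)
    sdp <- sqrt(rowMeans((m - mu)^2))   # population SD
    const <- sdp == 0 | is.na(sdp)
    if (any(const))
        message(sum(const), " constant row(s) dropped before z-scoring")
    z <- (m[!const, , drop = FALSE] - mu[!const]) / sdp[!const]
    attr(z, "dropped") <- rownames(m)[const]
    z
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then
# each next centre drawn with probability proportional to squared distance
# to the nearest chosen centre.
kmpp_centers <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- x[idx, ]
    if (k > 1L) {
        d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
        for (j in 2L:k) {
            if (all(d2 == 0)) idx <- sample.int(n, 1L)
            else idx <- sample.int(n, 1L, prob = d2)
            centers[j, ] <- x[idx, ]
            d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
        }
    }
    centers
}

#' k-means clustering of expression trends
#'
#' Euclidean k-means on z-scored stage profiles: \code{nInit} runs of
#' Lloyd's algorithm from k-means++ seedings, keeping the solution with
#' the lowest total within-cluster sum of squares. Cluster ids are
#' relabelled by descending cluster size, so the partition is stable
#' across equivalent solutions. Deterministic given \code{seed}.
#'
#' @param z gene x stage z-scored matrix (rows from [rowZScore()]).
#' @param k number of clusters (the analysis uses 12 fine-grained and 5
#'   representative clusters).
#' @param seed RNG seed (default 42).
#' @param nInit number of restarts (default 25).
#' @return a \linkS4class{TrendClusters}.
#' @export
kmeansTrends <- function(z, k, seed = 42, nInit = 25) {
    if (k < 1L) stop("k must be >= 1")
    if (nrow(z) < k) stop("k exceeds the number of genes")
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    best <- NULL
    for (r in seq_len(nInit)) {
        centers <- kmpp_centers(z, k)
        centers <- centers[!duplicated(round(centers, 12)), , drop = FALSE]
        km <- tryCatch(
            suppressWarnings(stats::kmeans(z, centers = centers,
                                           iter.max = 100L,
                                           algorithm = "Lloyd")),
            error = function(e) NULL)
        if (is.null(km) || anyNA(km$centers)) next
        if (is.null(best) || km$tot.withinss < best$tot.withinss)
            best <- km
    }
    if (is.null(best))
        stop("k-means failed to produce a valid solution")
    # relabel by descending size (ties by old label for determinism)
    sizes <- tabulate(best$cluster, nbins = nrow(best$centers))
    ord <- order(-sizes, seq_along(sizes))
    relabel <- integer(length(ord))
    relabel[ord] <- seq_along(ord)
    cl <- stats::setNames(as.integer(relabel[best$cluster]), rownames(z))
    centroids <- best$centers[ord, , drop = FALSE]
    rownames(centroids) <- seq_len(nrow(centroids))
    out <- new("TrendClusters", cluster = cl,
               centroids = centroids, k = as.integer(nrow(centroids)),
               seed = as.integer(seed), totWithinSS = best$tot.withinss,
               labels = character(nrow(centroids)))
    validObject(out)
    out
}

#' @describeIn kmeansTrends gene -> cluster id accessor.
#' @param x a TrendClusters.
#' @export
clusterAssignments <- function(x) {
    stopifnot(is(x, "TrendClusters"))
    x@cluster
}

#' @describeIn kmeansTrends centroid matrix accessor.
#' @export
centroids <- function(x) {
    stopifnot(is(x, "TrendClusters"))
    x@centroids
}

#' @describeIn kmeansTrends per-cluster trend labels (after
#'   [matchTrendTemplates()]).
#' @export
trendLabels <- function(x) {
    stopifnot(is(x, "TrendClusters"))
    stats::setNames(x@labels, seq_len(x@k))
}

setMethod("show", "TrendClusters", function(object) {
    cat("TrendClusters: k =", object@k, "over",
        length(object@cluster), "genes; inertia",
        format(object@totWithinSS, digits = 6), "\n")
    sizes <- tabulate(object@cluster, object@k)
    lab <- ifelse(nzchar(object@labels), paste0(" (", object@labels, ")"),
                  "")
    for (i in seq_len(object@k))
        cat("  cluster ", i, lab[i], ": ", sizes[i], " genes\n", sep = "")
})

#' Canonical five-stage trend templates
#'
#' z-scored versions of the five archetype shapes over the canonical
#' stages, used to label cluster centroids: early-only, early-pair,
#' increasing, mid-peak, late-pair.
#'
#' @return 5 x 5 matrix, one template per row.
#' @export
trendTemplates <- function() {
    shapes <- rbind(early_only = c(1, 0, 0, 0, 0),
                    early_pair = c(1, 1, 0, 0, 0),
                    increasing = c(1, 2, 3, 4, 5),
                    mid_peak = c(0, 1, 1, 0, 0),
                    late_pair = c(0, 0, 0, 1, 1))
    colnames(shapes) <- CANONICAL_STAGES
    t(apply(shapes, 1L, function(r) (r - mean(r)) / stats::sd(r)))
}

#' Label cluster centroids by their best-matching trend template
#'
#' Each centroid is labelled by the template with the highest Pearson
#' correlation; the correlation is reported. Ties are broken by template
#' priority order (the order of [trendTemplates()] rows) with a warning;
#' degenerate (constant) centroids and centroids not over the five
#' canonical stages get the label "custom".
#'
#' @param assignment a \linkS4class{TrendClusters}.
#' @return the TrendClusters with labels filled in; the label table
#'   (cluster, label, correlation) in \code{attr(, "matches")}.
#' @export
matchTrendTemplates <- function(assignment) {
    stopifnot(is(assignment, "TrendClusters"))
    cen <- centroids(assignment)
    tmpl <- trendTemplates()
    labels <- character(nrow(cen))
    corr <- rep(NA_real_, nrow(cen))
    if (ncol(cen) != ncol(tmpl)) {
        labels[] <- "custom"
    } else {
        for (i in seq_len(nrow(cen))) {
            v <- cen[i, ]
            if (stats::sd(v) == 0) {
                warning("constant centroid ", i, "; labelled 'custom'")
                labels[i] <- "custom"
                next
            }
            r <- apply(tmpl, 1L, function(tt) stats::cor(v, tt))
            best <- max(r)
            hits <- which(r >= best - 1e-12)
            if (length(hits) > 1L)
                warning("template tie for centroid ", i,
                        "; broken by priority order")
            labels[i] <- rownames(tmpl)[hits[1L]]
            corr[i] <- best
        }
    }
    assignment@labels <- labels
    attr(assignment, "matches") <- data.frame(
        cluster = seq_len(nrow(cen)), label = labels,
        correlation = corr, stringsAsFactors = FALSE)
    assignment
}
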