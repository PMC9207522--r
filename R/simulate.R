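#' Simulation configuration
#'
#' Parameters of the synthetic-data generator that emulates the statistical
#' structure of a staged bulk RNA-seq experiment: NB counts with planted
#' stage-trend archetypes, duplicate structure, library-size variation, and
#' a paralog-bearing orthology table with tunable directional concordance.
#'
#' @param nGenes number of genes.
#' @param stages ordered stage labels (default the five canonical oocyte
#'   groups).
#' @param nReps replicates per stage (default 2, as sequenced).
#' @param fractionNull fraction of flat (non-DE) genes.
#' @param effectFold fold change between high and low stages of a planted
#'   trend; a scalar, or length-2 range sampled log-uniformly per gene.
#' @param baselineRange range of baseline means (counts scale), sampled
#'   log-uniformly per gene.
#' @param dispMeanlog,dispSdlog log-normal parameters of the per-gene NB
#'   dispersion alpha (variance = mu + alpha mu^2).
#' @param sizeFactorRange range of per-sample size factors, sampled
#'   log-uniformly.
#' @param paralogFraction fraction of human genes carrying two zebrafish
#'   paralogs in the generated orthology table.
#' @param concordance probability that a both-DEG paralog pair shares its
#'   planted direction (default 0.8).
#' @param fractionUnannotated fraction of zebrafish genes with no human
#'   ortholog.
#' @param seed mandatory integer seed; one master seed drives independent
#'   sub-generator seeds.
#' @return a validated list of class \code{"oostage_sim_config"}.
#' @export
simConfig <- function(nGenes = 10000, stages = CANONICAL_STAGES, nReps = 2,
                      fractionNull = 0.5, effectFold = c(2, 8),
                      baselineRange = c(5, 500),
                      dispMeanlog = log(0.05), dispSdlog = 0.5,
                      sizeFactorRange = c(0.7, 1.4),
                      paralogFraction = 0.35, concordance = 0.8,
                      fractionUnannotated = 0.2, seed) {
    if (missing(seed) || is.null(seed))
        stop("config error: a seed is mandatory")
    if (nGenes <= 0)
        stop("config error: nGenes must be positive")
    if (length(stages) < 2)
        stop("config error: at least 2 stages")
    fracs <- c(fractionNull, paralogFraction, concordance,
               fractionUnannotated)
    if (any(fracs < 0 | fracs > 1))
        stop("config error: fractions must lie in [0,1]")
    if (length(effectFold) == 1L) effectFold <- rep(effectFold, 2L)
    if (any(effectFold < 1))
        stop("config error: effectFold must be >= 1")
    structure(list(nGenes = as.integer(nGenes), stages = stages,
                   nReps = as.integer(nReps),
                   fractionNull = fractionNull, effectFold = effectFold,
                   baselineRange = baselineRange,
                   dispMeanlog = dispMeanlog, dispSdlog = dispSdlog,
                   sizeFactorRange = sizeFactorRange,
                   paralogFraction = paralogFraction,
                   concordance = concordance,
                   fractionUnannotated = fractionUnannotated,
                   seed = as.integer(seed)),
              class = "oostage_sim_config")
}

# one master seed -> named sub-seeds so sub-generators are independently
# reproducible; all below 2^31
deriveSeeds <- function(seed, which = c("truth", "counts", "orthology",
                                        "sizefactors", "kmeans")) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    stats::setNames(sample.int(.Machine$integer.max, length(which)), which)
}

#' Planted trend archetype shapes
#'
#' Stage-multiplier templates over k stages for the five canonical
#' expression trends: early-only (high in the first stage), early-pair
#' (first two stages), increasing (monotone ramp), mid-peak (middle
#' stages), late-pair (last two stages). Multipliers are 1 for low stages
#' and \code{fold} for high stages (geometric ramp for "increasing").
#'
#' @param fold high/low expression ratio.
#' @param nStages number of stages (default 5).
#' @return matrix, one archetype per row.
#' @export
trendArchetypes <- function(fold, nStages = 5) {
    k <- nStages
    ramp <- fold^(seq(0, 1, length.out = k))
    mid <- rep(1, k)
    mid[ceiling(k / 2) + c(-1, 0)] <- fold
    shapes <- rbind(
        early_only = c(fold, rep(1, k - 1)),
        early_pair = c(fold, fold, rep(1, k - 2)),
        increasing = ramp,
        mid_peak = mid,
        late_pair = c(rep(1, k - 2), fold, fold))
    colnames(shapes) <- paste0("stage", seq_len(k))
    shapes
}

#' Generate the per-gene truth table
#'
#' Assigns each gene an archetype (0 = flat/null, 1..5 = trend shapes), a
#' baseline mean, a per-stage mean multiplier, an NB dispersion, and a
#' signed DEG truth (sign of the last-vs-first planted change; 0 for null
#' and for the symmetric mid-peak shape, whose end stages are unchanged).
#'
#' @param config a [simConfig()].
#' @return data.frame with one row per gene plus a "multipliers"
#'   gene x stage matrix in \code{attr(, "multipliers")}.
#' @export
generateTruth <- function(config) {
    stopifnot(inherits(config, "oostage_sim_config"))
    seeds <- deriveSeeds(config$seed)
    set.seed(seeds[["truth"]])
    n <- config$nGenes
    k <- length(config$stages)
    gene_id <- sprintf("gene%05d", seq_len(n))
    is_null <- stats::runif(n) < config$fractionNull
    archetype <- integer(n)
    archetype[!is_null] <- sample.int(5L, sum(!is_null), replace = TRUE)
    baseline <- exp(stats::runif(n, log(config$baselineRange[1]),
                                 log(config$baselineRange[2])))
    alpha <- stats::rlnorm(n, config$dispMeanlog, config$dispSdlog)
    fold <- exp(stats::runif(n, log(config$effectFold[1]),
                             log(config$effectFold[2])))
    mult <- matrix(1, n, k,
                   dimnames = list(gene_id, config$stages))
    for (i in which(!is_null)) {
        shapes <- trendArchetypes(fold[i], k)
        mult[i, ] <- shapes[archetype[i], ]
    }
    # signed truth: direction of the last-stage vs first-stage change
    lfc_ends <- log2(mult[, k] / mult[, 1])
    truth <- data.frame(gene_id = gene_id, archetype = archetype,
                        baseline = baseline, alpha = alpha,
                        fold = ifelse(is_null, 1, fold),
                        deg_sign = sign(lfc_ends),
                        stringsAsFactors = FALSE)
    attr(truth, "multipliers") <- mult
    truth
}

#' Generate NB counts from a truth table
#'
#' count_ij ~ NB(mean = baseline_i x multiplier_i,stage(j) x sizefactor_j,
#' dispersion alpha_i), Poisson in the alpha = 0 limit. Size factors are
#' drawn log-uniformly from the configured range, one per sample.
#'
#' @param truth output of [generateTruth()].
#' @param config the same [simConfig()].
#' @return a \linkS4class{StageExperiment}; the drawn size factors are in
#'   \code{metadata(se)$true_size_factors}.
#' @export
generateCounts <- function(truth, config) {
    stopifnot(inherits(config, "oostage_sim_config"))
    seeds <- deriveSeeds(config$seed)
    mult <- attr(truth, "multipliers")
    k <- length(config$stages)
    nrep <- config$nReps
    stage <- rep(config$stages, each = nrep)
    sample_id <- paste0(stage, "_rep", rep(seq_len(nrep), times = k))

    set.seed(seeds[["sizefactors"]])
    sf <- exp(stats::runif(length(stage), log(config$sizeFactorRange[1]),
                           log(config$sizeFactorRange[2])))

    set.seed(seeds[["counts"]])
    n <- nrow(truth)
    cts <- matrix(0L, n, length(stage),
                  dimnames = list(truth$gene_id, sample_id))
    for (j in seq_along(stage)) {
        mu <- truth$baseline * mult[, stage[j]] * sf[j]
        poi <- truth$alpha < 1e-12
        col <- integer(n)
        if (any(poi)) col[poi] <- stats::rpois(sum(poi), mu[poi])
        if (any(!poi)) col[!poi] <- stats::rnbinom(sum(!poi),
                                        size = 1 / truth$alpha[!poi],
                                        mu = mu[!poi])
        cts[, j] <- col
    }
    se <- StageExperiment(cts, stats::setNames(stage, sample_id),
                          stageLevels = config$stages)
    metadata(se)$true_size_factors <- stats::setNames(sf, sample_id)
    se
}

#' Generate a synthetic orthology table with planted concordance
#'
#' A configured fraction of human genes receive two zebrafish paralogs;
#' among paralog pairs where both members carry a planted DEG sign, the
#' signs agree with probability \code{concordance}. The remaining
#' zebrafish genes map 1:1, and a configured fraction are left
#' unannotated.
#'
#' @param config a [simConfig()].
#' @param degTruth data.frame with columns gene_id and deg_sign
#'   (+1 / -1 / 0), e.g. from [generateTruth()].
#' @return an \linkS4class{OrthologyTable}; planted pair records (zf_a,
#'   zf_b, human_gene, both_deg, concordant) in \code{attr(, "pairs")}.
#' @export
generateOrthology <- function(config, degTruth) {
    stopifnot(inherits(config, "oostage_sim_config"))
    seeds <- deriveSeeds(config$seed)
    set.seed(seeds[["orthology"]])
    genes <- degTruth$gene_id
    sgn <- stats::setNames(degTruth$deg_sign, genes)
    n <- length(genes)
    n_unann <- round(config$fractionUnannotated * n)
    unann <- sample(genes, n_unann)
    ann <- setdiff(genes, unann)
    # n_pairs/H = paralogFraction with 2*n_pairs + n_single = |ann|
    H <- length(ann) / (1 + config$paralogFraction)
    n_pairs <- round(config$paralogFraction * H)

    up <- sample(ann[sgn[ann] > 0])
    down <- sample(ann[sgn[ann] < 0])
    null <- sample(ann[sgn[ann] == 0])
    take <- function(pool_name) {
        pool <- get(pool_name, envir = parent.frame())
        g <- pool[1L]
        assign(pool_name, pool[-1L], envir = parent.frame())
        g
    }
    pairs <- NULL
    if (n_pairs > 0) {
        pair_a <- character(n_pairs); pair_b <- character(n_pairs)
        concord <- stats::runif(n_pairs) < config$concordance
        for (p in seq_len(n_pairs)) {
            pools <- c(up = length(up), down = length(down),
                       null = length(null))
            first <- sample(names(pools), 1L, prob = pools)
            a <- take(first)
            n_deg <- length(up) + length(down)
            second_deg <- first != "null" &&
                stats::runif(1) < n_deg / (n_deg + length(null))
            if (first == "null") {
                # concordance is defined over both-DEG pairs only
                pools <- c(up = length(up), down = length(down),
                           null = length(null))
                b <- take(sample(names(pools), 1L, prob = pools))
            } else if (second_deg) {
                same <- if (concord[p]) first else
                        setdiff(c("up", "down"), first)
                alt <- setdiff(c("up", "down"), same)
                b <- if (length(get(same)) > 0) take(same)
                     else if (length(get(alt)) > 0) take(alt)
                     else take("null")
            } else {
                b <- if (length(null) > 0) take("null")
                     else take(sample(c("up", "down"), 1L,
                               prob = c(length(up), length(down))))
            }
            pair_a[p] <- a; pair_b[p] <- b
        }
        pairs <- data.frame(zf_a = pair_a, zf_b = pair_b,
                            stringsAsFactors = FALSE)
    }
    singles <- c(up, down, null)
    hum_pair <- if (n_pairs > 0) sprintf("HUMP%05d", seq_len(n_pairs))
                else character()
    hum_single <- sprintf("HUMS%05d", seq_along(singles))
    zf <- c(if (n_pairs > 0) c(pairs$zf_a, pairs$zf_b), singles, unann)
    hum <- c(rep(hum_pair, 2L), hum_single, rep(NA_character_, n_unann))
    tab <- orthologyTable(zf, hum)
    if (!is.null(pairs)) {
        pairs$human_gene <- hum_pair
        pairs$both_deg <- sgn[pairs$zf_a] != 0 & sgn[pairs$zf_b] != 0
        pairs$concordant <- pairs$both_deg &
            sgn[pairs$zf_a] == sgn[pairs$zf_b]
        attr(tab, "pairs") <- pairs
    }
    tab
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Convenience wrapper running [generateTruth()], [generateCounts()] and
#' [generateOrthology()] under one seed.
#'
#' @param config a [simConfig()].
#' @param outDir if non-NULL, writes counts.tsv, design.tsv,
#'   orthology.tsv and truth.tsv there.
#' @return list(se, truth, orthology).
#' @export
simulateDataset <- function(config, outDir = NULL) {
    truth <- generateTruth(config)
    se <- generateCounts(truth, config)
    ortho <- generateOrthology(config, truth)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeCountMatrix(se, file.path(outDir, "counts.tsv"),
                         file.path(outDir, "design.tsv"))
        writeOrthologyTable(ortho, file.path(outDir, "orthology.tsv"))
        utils::write.table(truth, file.path(outDir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(se = se, truth = truth, orthology = ortho)
}
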