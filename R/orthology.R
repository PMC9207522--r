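#' Partition an orthology table into 1:1 / one-to-many / unannotated
#'
#' A zebrafish gene is one_to_many iff at least two zebrafish genes share
#' its human ortholog (the teleost genome duplication leaves many human
#' genes with two zebrafish paralogs); one_to_one otherwise; unannotated
#' when it has no curated human ortholog. The partition is a function of
#' the table alone.
#'
#' @param table an \linkS4class{OrthologyTable}.
#' @return list with the per-gene relation vector and the counts
#'   n_annotated, n_one_to_one, n_one_to_many, n_unannotated plus
#'   fraction_one_to_one / fraction_one_to_many (percent of annotated
#'   genes; NA on an empty table).
#' @export
partitionOrthology <- function(table) {
    m <- orthologyMapping(table)
    n11 <- sum(m$relation == "one_to_one")
    n1m <- sum(m$relation == "one_to_many")
    nann <- n11 + n1m
    list(relation = stats::setNames(m$relation, m$zf_gene),
         n_annotated = nann, n_one_to_one = n11, n_one_to_many = n1m,
         n_unannotated = sum(m$relation == "unannotated"),
         fraction_one_to_one = if (nann > 0) 100 * n11 / nann else
             NA_real_,
         fraction_one_to_many = if (nann > 0) 100 * n1m / nann else
             NA_real_)
}

#' Collapse a signed zebrafish DEG set to human nomenclature
#'
#' 1:1 DEGs take their human ortholog directly. For a human gene with
#' several zebrafish orthologs, only the zebrafish genes present in the
#' DEG set are considered (paralogs that are not significant do not veto):
#' if all those DEGs changed in the same direction the human gene is
#' included with that direction; opposite significant changes produce a
#' conflict record and the human gene is omitted. DEGs without a curated
#' human ortholog become unresolved records. Every zebrafish DEG lands in
#' exactly one of included-contributor / conflict / unresolved.
#'
#' @param degs a signed (pairwise) \linkS4class{DEGSet}; genes with
#'   direction 0 or NA are excluded with a warning (no printed rule covers
#'   them).
#' @param table an \linkS4class{OrthologyTable}.
#' @return a \linkS4class{CollapsedDEGSet}.
#' @export
directionalityCollapse <- function(degs, table) {
    stopifnot(is(degs, "DEGSet"))
    g <- degGenes(degs)
    if (all(is.na(g$direction)) && nrow(g) > 0)
        stop("the directionality collapse needs a signed pairwise DEG ",
             "set; LRT membership carries no direction")
    unsigned <- is.na(g$direction) | g$direction == 0
    if (any(unsigned)) {
        warning(sum(unsigned), " DEG(s) with zero/undefined direction ",
                "excluded from the collapse")
        g <- g[!unsigned, , drop = FALSE]
    }
    m <- orthologyMapping(table)
    hum <- stats::setNames(m$human_gene, m$zf_gene)
    known <- g$gene_id %in% m$zf_gene
    if (any(!known))
        warning(sum(!known), " DEG(s) absent from the orthology table; ",
                "treated as unannotated")
    h <- ifelse(known, hum[g$gene_id], NA_character_)

    unres <- is.na(h)
    unresolved <- data.frame(zf_gene = g$gene_id[unres],
                             direction = g$direction[unres],
                             row.names = NULL, stringsAsFactors = FALSE)
    gd <- g[!unres, , drop = FALSE]
    hd <- h[!unres]
    included <- conflicts <- NULL
    if (nrow(gd)) {
        sp <- split(seq_len(nrow(gd)), hd)
        rows_inc <- lapply(names(sp), function(hg) {
            idx <- sp[[hg]]
            dirs <- gd$direction[idx]
            if (length(unique(dirs)) == 1L)
                data.frame(human_gene = hg, direction = dirs[1L],
                           zf_contributors = paste(gd$gene_id[idx],
                                                   collapse = ","),
                           n_contributors = length(idx),
                           stringsAsFactors = FALSE)
            else NULL
        })
        rows_con <- lapply(names(sp), function(hg) {
            idx <- sp[[hg]]
            dirs <- gd$direction[idx]
            if (length(unique(dirs)) > 1L)
                data.frame(human_gene = hg,
                           zf_genes = paste(gd$gene_id[idx],
                                            collapse = ","),
                           directions = paste(dirs, collapse = ","),
                           stringsAsFactors = FALSE)
            else NULL
        })
        included <- do.call(rbind, rows_inc)
        conflicts <- do.call(rbind, rows_con)
    }
    empty_inc <- data.frame(human_gene = character(),
                            direction = integer(),
                            zf_contributors = character(),
                            n_contributors = integer(),
                            stringsAsFactors = FALSE)
    empty_con <- data.frame(human_gene = character(),
                            zf_genes = character(),
                            directions = character(),
                            stringsAsFactors = FALSE)
    out <- new("CollapsedDEGSet",
               included = if (is.null(included)) empty_inc else included,
               conflicts = if (is.null(conflicts)) empty_con else conflicts,
               unresolved = unresolved,
               contrast = degs@contrast)
    validObject(out)
    out
}

#' @describeIn directionalityCollapse included human genes accessor.
#' @param x a CollapsedDEGSet.
#' @export
includedGenes <- function(x) {
    stopifnot(is(x, "CollapsedDEGSet"))
    x@included
}

#' @describeIn directionalityCollapse conflict records accessor.
#' @export
conflictGenes <- function(x) {
    stopifnot(is(x, "CollapsedDEGSet"))
    x@conflicts
}

#' @describeIn directionalityCollapse unresolved (unannotated) records.
#' @export
unresolvedGenes <- function(x) {
    stopifnot(is(x, "CollapsedDEGSet"))
    x@unresolved
}

setMethod("show", "CollapsedDEGSet", function(object) {
    cat("CollapsedDEGSet (contrast ", object@contrast, "): ",
        nrow(object@included), " human genes included, ",
        nrow(object@conflicts), " conflicts, ",
        nrow(object@unresolved), " unresolved\n", sep = "")
})

#' Ortholog-conversion coverage arithmetic
#'
#' Effective ortholog coverage of a one-to-many-aware conversion:
#' the 1:1 fraction passes through directly, and of the one-to-many
#' fraction only the directionally concordant part survives, so
#' effective coverage = fraction_one_to_one +
#' concordant x fraction_one_to_many (all in percent of annotated genes);
#' the residual requires manual investigation.
#'
#' @param nOneToOne,nOneToMany,nAnnotated gene counts; nAnnotated is the
#'   denominator (the annotated genes).
#' @param nTotal optional total gene count, for the annotated fraction.
#' @param concordantFraction fraction (0-1) of one-to-many cases whose
#'   significant members agree in direction.
#' @return list of percentages: fraction_one_to_one,
#'   fraction_one_to_many, annotated_fraction (NA without nTotal),
#'   effective_coverage, residual_fraction.
#' @export
orthologCoverage <- function(nOneToOne, nOneToMany, nAnnotated,
                             nTotal = NA, concordantFraction) {
    f11 <- 100 * nOneToOne / nAnnotated
    f1m <- 100 * nOneToMany / nAnnotated
    eff <- f11 + concordantFraction * f1m
    list(fraction_one_to_one = f11,
         fraction_one_to_many = f1m,
         annotated_fraction = if (is.na(nTotal)) NA_real_ else
             100 * nAnnotated / nTotal,
         concordant_fraction = 100 * concordantFraction,
         effective_coverage = eff,
         residual_fraction = 100 - eff)
}

#' Coverage statistics of a collapse run
#'
#' Combines the table partition with the measured directional concordance
#' among the paralog groups that contained at least two significant
#' members, and derives the effective coverage via [orthologCoverage()].
#'
#' @param table the \linkS4class{OrthologyTable}.
#' @param degs the signed \linkS4class{DEGSet} that was collapsed.
#' @param collapsed the resulting \linkS4class{CollapsedDEGSet}.
#' @return list: the partition counts, concordant_fraction measured over
#'   multi-DEG paralog groups (NA when there were none), and the
#'   effective-coverage percentages.
#' @export
coverageStatistics <- function(table, degs, collapsed) {
    part <- partitionOrthology(table)
    inc <- includedGenes(collapsed)
    con <- conflictGenes(collapsed)
    multi_ok <- sum(inc$n_contributors >= 2L)
    n_multi <- multi_ok + nrow(con)
    concord <- if (n_multi > 0) multi_ok / n_multi else NA_real_
    cov <- if (!is.na(concord))
        orthologCoverage(part$n_one_to_one, part$n_one_to_many,
                         part$n_annotated,
                         part$n_annotated + part$n_unannotated,
                         concord)
    else NULL
    c(part[c("n_annotated", "n_one_to_one", "n_one_to_many",
             "n_unannotated", "fraction_one_to_one",
             "fraction_one_to_many")],
      list(n_multi_deg_groups = n_multi,
           concordant_fraction = if (is.na(concord)) NA_real_ else
               100 * concord),
      cov[c("annotated_fraction", "effective_coverage",
            "residual_fraction")])
}
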