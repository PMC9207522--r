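#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of each gene set against a
#' query (e.g. a collapsed human DEG list) over a background universe:
#' p = P[overlap >= observed] when drawing |query| genes without
#' replacement from the background. Terms are intersected with the
#' background before testing; p-values are BH-adjusted across the tested
#' terms.
#'
#' @param query character vector of genes (must be a subset of
#'   \code{background}).
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param background gene universe. Defaults to the tested universe is the
#'   caller's responsibility; a common choice is all human genes produced
#'   by the collapse.
#' @param fdrCut FDR threshold for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame term, overlap, term_size, query_size,
#'   background_size, pvalue, fdr, significant — all tested terms, sorted
#'   by p-value.
#' @export
hypergeometricORA <- function(query, sets, background, fdrCut = 0.05) {
    query <- unique(query)
    background <- unique(background)
    bad <- setdiff(query, background)
    if (length(bad))
        stop("query genes absent from the background: ",
             paste(utils::head(bad, 10), collapse = ", "))
    N <- length(background)
    q <- length(query)
    rows <- lapply(names(sets), function(term) {
        tset <- intersect(unique(sets[[term]]), background)
        K <- length(tset)
        if (K == 0L) return(NULL)
        k <- length(intersect(tset, query))
        # upper tail including the observed overlap
        p <- stats::phyper(k - 1, K, N - K, q, lower.tail = FALSE)
        data.frame(term = term, overlap = k, term_size = K,
                   query_size = q, background_size = N,
                   pvalue = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(), overlap = integer(),
                          term_size = integer(), query_size = integer(),
                          background_size = integer(), pvalue = numeric(),
                          fdr = numeric(), significant = logical(),
                          stringsAsFactors = FALSE))
    out$fdr <- bhAdjust(out$pvalue)
    out$significant <- out$fdr < fdrCut
    out[order(out$pvalue, out$term), , drop = FALSE]
}
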