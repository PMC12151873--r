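#' Select a query probe set from a fit by significance, direction and effect
#'
#' Probes with q below the threshold, slope sign matching the requested
#' direction, and effect magnitude at least `effectThresh`, where the
#' effect is `slope_per_year * referenceDuration` (total methylation change
#' over a reference duration in years).  With `effectThresh = 0` the
#' selection reduces to the q-and-sign filter.  The default 0.15 magnitude
#' cutoff mirrors the stricter thresholding used for enrichment queries on
#' arrays that over-represent promoter/enhancer CpGs; reproducing specific
#' query sizes may require calibrating `referenceDuration` to the scale the
#' effect is measured on.
#'
#' @param fits a \linkS4class{SiteWiseFit} or \linkS4class{InteractionFit}
#'   (for the latter, slope and q refer to the interaction coefficient).
#' @param direction `"gain"` (positive slopes) or `"loss"` (negative).
#' @param qThresh strict q cutoff, default 0.05.
#' @param effectThresh nonnegative methylation-fraction magnitude cutoff,
#'   default 0.15.
#' @param referenceDuration duration in years converting per-year slopes to
#'   effects, default 1.
#' @return character vector of probe ids.
#' @export
selectQuery <- function(fits, direction = c("gain", "loss"),
                        qThresh = 0.05, effectThresh = 0.15,
                        referenceDuration = 1) {
    direction <- match.arg(direction)
    if (effectThresh < 0) stop("effectThresh must be nonnegative")
    r <- fitResults(fits)
    if (is(fits, "SiteWiseFit")) {
        slope <- r$slope_per_year
        q <- r$q_age
    } else {
        slope <- r$age_env_coef
        q <- r$q_int
    }
    effect <- slope * referenceDuration
    keep <- !is.na(q) & q < qThresh &
        if (direction == "gain") slope > 0 & effect >= effectThresh
        else slope < 0 & effect <= -effectThresh
    r$probe_id[keep]
}

# Exact one-sided hypergeometric upper tail P(X >= overlap): equivalent to
# the one-sided (greater) Fisher exact test on the 2x2 membership table.
.hyperTailP <- function(overlap, nSet, nUniverse, nQuery) {
    if (nSet == 0L || nQuery == 0L) return(1)
    stats::phyper(overlap - 1, nSet, nUniverse - nSet, nQuery,
                  lower.tail = FALSE)
}

#' Probe-set enrichment of a query against a background universe
#'
#' For each probe set (intersected with the universe first), builds the 2x2
#' table (overlap, query-only, set-only, rest) and computes the one-sided
#' Fisher exact p-value -- the hypergeometric upper tail
#' `P(X >= overlap)` -- together with the log2 odds ratio of the table.
#' BH q-values are computed across the collection and records are sorted by
#' p.  Depletion can be tested instead via `alternative = "less"`.
#'
#' @param query character vector of probe ids; must be drawn from
#'   `universe`.
#' @param sets named list of character vectors (e.g. from
#'   [readProbeSets()]).
#' @param universe character vector, the background probe universe (e.g.
#'   all cg probes tested).
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return data.frame with one row per set: `set`, `n_universe`, `n_set`,
#'   `n_query`, `n_overlap`, `log2_odds_ratio`, `p`, `q`, sorted by `p`.
#' @export
testEnrichment <- function(query, sets, universe,
                           alternative = c("greater", "less")) {
    alternative <- match.arg(alternative)
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    query <- unique(query)
    if (!length(query)) stop("empty query")
    bad <- setdiff(query, universe)
    if (length(bad))
        stop(length(bad), " query probes are not in the universe")
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("sets must be a uniquely named list")
    nU <- length(universe)
    nQ <- length(query)
    inQuery <- universe %in% query
    rows <- lapply(names(sets), function(nm) {
        members <- unique(sets[[nm]])
        inSet <- universe %in% members
        nS <- sum(inSet)
        a <- sum(inSet & inQuery)
        b <- nQ - a
        cc <- nS - a
        d <- nU - a - b - cc
        p <- if (alternative == "greater") .hyperTailP(a, nS, nU, nQ)
             else stats::phyper(a, nS, nU - nS, nQ, lower.tail = TRUE)
        lor <- if (nS == 0L) NA_real_ else log2((a * d) / (b * cc))
        data.frame(set = nm, n_universe = nU, n_set = nS, n_query = nQ,
                   n_overlap = a, log2_odds_ratio = lor, p = p)
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    out <- out[order(out$p, out$set), , drop = FALSE]
    rownames(out) <- NULL
    out
}
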