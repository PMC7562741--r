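#' Fisher-exact over-representation of a gene list in one category
#'
#' Builds the 2x2 table a = |list & category|, b = |list \\ category|,
#' c = |category \\ list| (within the universe), d = remainder, and reports
#' the right-sided hypergeometric p-value P(X >= a), the sample odds ratio
#' OR = ad/(bc), and a 95\% Woolf (log-normal) confidence interval. When
#' any cell is zero the Haldane-Anscombe 0.5 correction is applied to all
#' four cells for the CI only. An empty overlap (a = 0) is reported as
#' OR = 0 and flagged `"plot-upper-bound"`, the convention under which such
#' categories are drawn at the upper CI bound on forest plots; b = 0 or
#' c = 0 gives OR = Inf.
#'
#' @param list character vector of genes (must be a subset of `universe`).
#' @param category character vector of genes; intersected with the
#'   universe before counting.
#' @param universe character vector of all eligible genes.
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame: category size counts a, b, c, d, `or`,
#'   `ciLow`, `ciHigh`, `p`, `flag`.
#' @export
fisherEnrichment <- function(list, category, universe, conf = 0.95) {
    if (!length(universe)) stop("empty universe")
    if (!length(list)) stop("empty gene list")
    if (!all(list %in% universe))
        stop("gene list must be a subset of the universe")
    cat2 <- intersect(category, universe)
    if (!length(cat2)) stop("category is disjoint from the universe")
    a <- length(intersect(list, cat2))
    b <- length(list) - a
    c <- length(cat2) - a
    d <- length(universe) - a - b - c
    .fisherRecord(a, b, c, d, conf)
}

# core computation from 2x2 counts (exported for oracle-style testing on
# arbitrary tables)
#' @rdname fisherEnrichment
#' @param a,b,c,d 2x2 table counts (list-in-category, list-out,
#'   category-only, remainder).
#' @export
fisherTable <- function(a, b, c, d, conf = 0.95) {
    .fisherRecord(a, b, c, d, conf)
}

.fisherRecord <- function(a, b, c, d, conf = 0.95) {
    N <- a + b + c + d
    K <- a + c          # category size within universe
    n <- a + b          # list size
    p <- phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    or <- if (a == 0) 0 else if (b == 0 || c == 0) Inf else
        (a * d) / (b * c)
    cells <- c(a, b, c, d)
    if (any(cells == 0)) cells <- cells + 0.5
    zq <- qnorm(1 - (1 - conf) / 2)
    lo <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
    sel <- zq * sqrt(sum(1 / cells))
    flag <- if (a == 0) "plot-upper-bound" else ""
    data.frame(a = a, b = b, c = c, d = d, or = or,
               ciLow = exp(lo - sel), ciHigh = exp(lo + sel), p = p,
               flag = flag, stringsAsFactors = FALSE)
}

#' Enrichment of a gene list against every category of a taxonomy
#'
#' Runs [fisherEnrichment()] per category and returns the records sorted by
#' p-value. A category is marked significant when p < alpha and its 95\% CI
#' excludes OR = 1. Per-category errors (e.g. a category disjoint from the
#' universe) are returned as flagged records rather than failing the run.
#'
#' @param list character vector of genes.
#' @param taxonomy named list of gene categories (e.g. from [readGMT()] or
#'   [generateTaxonomy()]).
#' @param universe character vector of all eligible genes (default policy:
#'   all genes surviving low-intensity filtering).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per category, sorted by p.
#' @export
enrichAll <- function(list, taxonomy, universe, alpha = 0.05) {
    recs <- lapply(names(taxonomy), function(nm) {
        r <- tryCatch(fisherEnrichment(list, taxonomy[[nm]], universe),
                      error = function(e) data.frame(
                          a = NA_integer_, b = NA_integer_, c = NA_integer_,
                          d = NA_integer_, or = NA_real_, ciLow = NA_real_,
                          ciHigh = NA_real_, p = NA_real_,
                          flag = paste0("error: ", conditionMessage(e)),
                          stringsAsFactors = FALSE))
        cbind(category = nm, r, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    out$significant <- !is.na(out$p) & out$p < alpha &
        (out$ciLow > 1 | out$ciHigh < 1)
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Forest-plot export of enrichment records
#'
#' Returns plotting coordinates on a log2 odds-ratio axis, with the
#' OR = 0 convention: categories with empty overlap are positioned at
#' their CI upper bound.
#'
#' @param records data.frame from [enrichAll()].
#' @return data.frame with category, x (log2 position), xLow, xHigh,
#'   significant.
#' @export
forestData <- function(records) {
    x <- ifelse(records$or == 0, records$ciHigh, records$or)
    data.frame(category = records$category, x = log2(x),
               xLow = log2(records$ciLow), xHigh = log2(records$ciHigh),
               significant = records$significant,
               stringsAsFactors = FALSE)
}
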