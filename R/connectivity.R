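#' Filter a perturbagen connectivity table by score range
#'
#' Keeps rows whose connectivity score falls in the admissible range for
#' their perturbation type: compounds and knock-downs in [-100, -75]
#' (programs opposing the query signature) and overexpressions in
#' [50, 100]. Boundaries are inclusive. Filtering is idempotent.
#'
#' @param table data.frame with columns perturbagen, type
#'   (compound/KD/OE), score, target, moa_direction.
#' @param compoundRange,kdRange,oeRange inclusive score intervals.
#' @return the filtered table.
#' @export
filterConnectivity <- function(table, compoundRange = c(-100, -75),
                               kdRange = c(-100, -75),
                               oeRange = c(50, 100)) {
    .checkConnectivity(table)
    ranges <- list(compound = compoundRange, KD = kdRange, OE = oeRange)
    keep <- vapply(seq_len(nrow(table)), function(i) {
        r <- ranges[[table$type[i]]]
        table$score[i] >= r[1] && table$score[i] <= r[2]
    }, logical(1))
    out <- table[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.checkConnectivity <- function(table) {
    need <- c("perturbagen", "type", "score", "target")
    if (!all(need %in% colnames(table)))
        stop("connectivity table needs columns: ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(table$type), c("compound", "KD", "OE"))
    if (length(bad)) stop("unknown perturbation type: ", bad[1])
    if (any(table$score < -100 | table$score > 100))
        stop("connectivity scores must lie in [-100, 100]")
    invisible(TRUE)
}

#' Check agonist/antagonist direction consistency per target
#'
#' A target passes when the scores of its agonists and its antagonists do
#' not both lie on the same side of zero (opposite pharmacology should
#' produce opposite connectivity). Targets with compounds in only one
#' direction pass vacuously and are flagged; rows with missing direction
#' are skipped with a note.
#'
#' @param table filtered connectivity table with a `moa_direction` column.
#' @return data.frame: target, pass, flag.
#' @export
checkDirectionConsistency <- function(table) {
    targets <- unique(table$target[!is.na(table$target)])
    rows <- lapply(targets, function(tg) {
        sub <- table[!is.na(table$target) & table$target == tg, ]
        note <- if (anyNA(sub$moa_direction)) "NA directions skipped" else ""
        ago <- sub$score[!is.na(sub$moa_direction) &
                         sub$moa_direction == "agonist"]
        anta <- sub$score[!is.na(sub$moa_direction) &
                          sub$moa_direction == "antagonist"]
        if (!length(ago) || !length(anta)) {
            pass <- TRUE
            note <- paste(note, "single direction: vacuous pass")
        } else {
            sameSide <- (all(ago > 0) && all(anta > 0)) ||
                (all(ago < 0) && all(anta < 0))
            pass <- !sameSide
        }
        data.frame(target = tg, pass = pass, flag = trimws(note),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Summarize filtered compounds by drug target
#'
#' For every target with at least `minCount` compounds surviving the score
#' filter and the direction-consistency check: compound count, score range
#' (min, max), arithmetic mean, SEM (sample sd over sqrt(n)), and the top
#' compound (most negative score, ties broken by perturbagen id). Sorted
#' by mean ascending (strongest opposition first).
#'
#' @param table filtered connectivity table.
#' @param minCount minimum compounds per reported target (default 2).
#' @param checkDirections exclude direction-inconsistent targets first
#'   (default TRUE).
#' @return data.frame: target, n, scoreMin, scoreMax, mean, sem,
#'   topCompound.
#' @export
summarizeTargets <- function(table, minCount = 2L, checkDirections = TRUE) {
    empty <- data.frame(target = character(), n = integer(),
                        scoreMin = numeric(), scoreMax = numeric(),
                        mean = numeric(), sem = numeric(),
                        topCompound = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(table)) return(empty)
    tab <- table[!is.na(table$target), , drop = FALSE]
    if (checkDirections && nrow(tab)) {
        cons <- checkDirectionConsistency(tab)
        tab <- tab[tab$target %in% cons$target[cons$pass], , drop = FALSE]
    }
    if (!nrow(tab)) return(empty)
    rows <- lapply(split(tab, tab$target), function(sub) {
        if (nrow(sub) < minCount) return(NULL)
        ord <- order(sub$score, sub$perturbagen)
        data.frame(target = sub$target[1], n = nrow(sub),
                   scoreMin = min(sub$score), scoreMax = max(sub$score),
                   mean = mean(sub$score),
                   sem = sd(sub$score) / sqrt(nrow(sub)),
                   topCompound = sub$perturbagen[ord[1]],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(empty)
    out <- out[order(out$mean), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Round half-to-even at a given number of decimals
#'
#' Reporting convention for target summaries (banker's rounding at two
#' decimals), applied through an exact decimal representation so values
#' ending in 5 round to the even neighbour regardless of binary
#' representation.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded vector.
#' @export
roundHalfEven <- function(x, digits = 2L) {
    s <- 10^digits
    y <- x * s
    # snap to the nearest representable decimal before the parity decision
    ysnap <- round(y, 6)
    lo <- floor(ysnap)
    frac <- ysnap - lo
    up <- frac > 0.5 | (frac == 0.5 & lo %% 2 != 0)
    (lo + as.numeric(up)) / s
}

#' Format a target summary for reporting
#'
#' @param summary data.frame from [summarizeTargets()].
#' @return data.frame with mean and sem rounded half-even to 2 decimals
#'   and a printed range column.
#' @export
formatTargetTable <- function(summary) {
    data.frame(target = summary$target, count = summary$n,
               range = sprintf("(%.2f)-(%.2f)",
                               roundHalfEven(summary$scoreMin),
                               roundHalfEven(summary$scoreMax)),
               mean = roundHalfEven(summary$mean),
               sem = roundHalfEven(summary$sem),
               topCompound = summary$topCompound,
               stringsAsFactors = FALSE)
}

#' Rank biological upstream regulators from KD/OE connectivity rows
#'
#' Regulators already inside the admitted score ranges are ranked by
#' absolute connectivity score, descending; knock-down and overexpression
#' entries for the same gene are kept as separate evidence lines. Ties
#' break by perturbagen id.
#'
#' @param table filtered connectivity table (KD/OE rows used).
#' @param topN number of regulators to return (default 50).
#' @return data.frame: perturbagen, type, score, rank.
#' @export
rankRegulators <- function(table, topN = 50L) {
    sub <- table[table$type %in% c("KD", "OE"), , drop = FALSE]
    if (!nrow(sub))
        return(data.frame(perturbagen = character(), type = character(),
                          score = numeric(), rank = integer(),
                          stringsAsFactors = FALSE))
    ord <- order(-abs(sub$score), sub$perturbagen)
    sub <- sub[ord[seq_len(min(topN, nrow(sub)))],
               c("perturbagen", "type", "score"), drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    rownames(sub) <- NULL
    sub
}
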