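#' Per-gene per-sample expression statistic for gene-set scoring
#'
#' The preliminary step of the per-sample KS-random-walk scoring: each
#' expression value is converted to a smoothed empirical CDF statistic
#' \deqn{\hat z_{ij} = (1/n) \sum_k \Phi((x_{ij} - x_{ik}) / h_i)}
#' with Gaussian kernel bandwidth h_i = s_i / 4 per gene, then genes are
#' ranked within each sample by decreasing statistic and given the
#' symmetric rank weight |p/2 - rank| (p = gene count). Genes constant
#' across all samples are excluded with a warning.
#'
#' @param bundle an [ExpressionBundle-class] with >= 3 samples.
#' @return list with `stat` (genes x samples), `ranks` (1 = largest
#'   statistic), `weights` (symmetric rank weights), `genes`.
#' @export
expressionStatistic <- function(bundle) {
    m <- exprValues(bundle)
    if (ncol(m) < 3L) stop("need at least 3 samples")
    constant <- apply(m, 1L, sd) == 0
    if (any(constant)) {
        warning(sum(constant), " constant gene(s) excluded from scoring")
        m <- m[!constant, , drop = FALSE]
    }
    if (!nrow(m)) stop("no variable genes left to score")
    n <- ncol(m)
    h <- apply(m, 1L, sd) / 4
    z <- t(vapply(seq_len(nrow(m)), function(i) {
        xi <- m[i, ]
        colMeans(pnorm(outer(xi, xi, FUN = function(k, j) (j - k))/h[i]))
    }, numeric(n)))
    dimnames(z) <- dimnames(m)
    p <- nrow(z)
    ranks <- apply(-z, 2L, rank, ties.method = "first")
    weights <- abs(p / 2 - ranks)
    list(stat = z, ranks = ranks, weights = weights, genes = rownames(m))
}

#' Per-sample gene-set enrichment scores via a weighted KS random walk
#'
#' For each sample, genes are traversed in decreasing order of the kernel
#' statistic; steps on in-set genes add the gene's rank weight raised to
#' `tau` (normalized by the in-set total), steps on out-of-set genes
#' subtract 1/(p - |set|). The `"diff"` score is the maximum positive
#' deviation of the walk plus the minimum negative deviation (each clamped
#' at 0); `"max"` returns the single deviation of largest magnitude.
#' Scores lie strictly inside (-1, 1).
#'
#' @param stats result of [expressionStatistic()].
#' @param geneSets named list of character vectors; each set must overlap
#'   the scored genes and not exhaust them.
#' @param tau rank-weight exponent (default 1).
#' @param mode `"diff"` or `"max"`.
#' @return score matrix, gene sets x samples, with scoring parameters in
#'   attributes.
#' @export
enrichmentScores <- function(stats, geneSets, tau = 1,
                             mode = c("diff", "max")) {
    mode <- match.arg(mode)
    genes <- stats$genes
    p <- length(genes)
    scores <- matrix(NA_real_, length(geneSets), ncol(stats$ranks),
                     dimnames = list(names(geneSets),
                                     colnames(stats$ranks)))
    for (s in seq_along(geneSets)) {
        inSet <- genes %in% geneSets[[s]]
        k <- sum(inSet)
        if (k == 0L || k == p)
            stop("gene set '", names(geneSets)[s],
                 "' is empty or spans all genes after matching")
        for (j in seq_len(ncol(stats$ranks))) {
            ord <- order(stats$ranks[, j])
            scores[s, j] <- .ksWalk(inSet[ord],
                                    stats$weights[ord, j], tau, mode)
        }
    }
    attr(scores, "params") <- list(tau = tau, mode = mode,
                                   bandwidthRule = "sd/4")
    scores
}

# one weighted KS walk down an ordered gene list
.ksWalk <- function(inSet, weights, tau, mode) {
    p <- length(inSet)
    w <- weights[inSet]^tau
    step <- numeric(p)
    step[inSet] <- w / sum(w)
    step[!inSet] <- -1 / (p - sum(inSet))
    v <- cumsum(step)
    if (mode == "diff") max(0, max(v)) + min(0, min(v)) else
        v[which.max(abs(v))]
}

#' Cohort contrasts of gene-set scores: Welch t and Hedges g
#'
#' Per gene set, compares case vs control score means with Welch's t test
#' (Satterthwaite degrees of freedom) and reports the Hedges g effect size
#' with the small-sample correction J = 1 - 3/(4(n1 + n2 - 2) - 1) applied
#' to the pooled-SD standardized mean difference.
#'
#' @param scores matrix from [enrichmentScores()] (sets x samples).
#' @param cohort binary vector over the score columns (1 = case).
#' @param alpha significance level (default 0.05).
#' @return data.frame: set, meanCase, meanControl, t, df, p, g,
#'   significant.
#' @export
compareGroups <- function(scores, cohort, alpha = 0.05) {
    if (length(cohort) != ncol(scores))
        stop("cohort must have one entry per score column")
    i1 <- cohort == 1; i2 <- cohort == 0
    n1 <- sum(i1); n2 <- sum(i2)
    if (n1 < 2L || n2 < 2L) stop("each cohort needs at least 2 samples")
    rows <- lapply(rownames(scores), function(s) {
        x <- scores[s, i1]; y <- scores[s, i2]
        v1 <- var(x) / n1; v2 <- var(y) / n2
        se <- sqrt(v1 + v2)
        dm <- mean(x) - mean(y)
        if (se == 0) {               # both groups constant
            tt <- if (dm == 0) 0 else sign(dm) * Inf
            df <- NA_real_
            p <- if (dm == 0) 1 else 0
        } else {
            tt <- dm / se
            df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
            p <- 2 * pt(-abs(tt), df)
        }
        data.frame(set = s, meanCase = mean(x), meanControl = mean(y),
                   t = tt, df = df, p = p, g = hedgesG(x, y),
                   significant = p < alpha, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Hedges g with small-sample correction
#'
#' g = J (mean(x) - mean(y)) / s_pooled with
#' s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)) and
#' J = 1 - 3 / (4 (n1 + n2 - 2) - 1).
#'
#' @param x,y numeric vectors (case, control).
#' @return corrected standardized mean difference.
#' @export
hedgesG <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df)
    J <- 1 - 3 / (4 * df - 1)
    dm <- mean(x) - mean(y)
    if (sp == 0) return(if (dm == 0) 0 else sign(dm) * Inf)
    J * dm / sp
}
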