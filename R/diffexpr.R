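#' Empirical-Bayes moderated two-group differential expression
#'
#' Fits the standard hierarchical model for per-gene variances in a
#' two-group comparison: gene-wise residual variances s2_g (d_g degrees of
#' freedom) are shrunk toward a prior variance s0^2 with d0 prior degrees
#' of freedom, giving the posterior variance
#' \deqn{s^2_{post} = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g)}
#' and the moderated statistic
#' \deqn{t = LFC / (s_{post} \sqrt{1/n_1 + 1/n_2})}
#' referred to a t distribution on d0 + d_g degrees of freedom. When no
#' prior is supplied, (d0, s0^2) are estimated by closed-form moment
#' matching of the scaled-F model on log s2_g. d0 = 0 reduces to the
#' ordinary pooled two-sample t; d0 = Inf gives a z-statistic with fixed
#' variance s0^2.
#'
#' @param bundle an [ExpressionBundle-class]; the contrast is case (cohort
#'   1) minus control (cohort 0), each with >= 2 samples.
#' @param prior optional list `list(d0 =, s02 =)` overriding estimation.
#' @param fdr BH-adjusted significance gate (default 0.2, chosen a priori
#'   to avoid excluding false negatives in small cohorts).
#' @param source annotation source tag stored with each row.
#' @return a [DEResult-class].
#' @export
fitModerated <- function(bundle, prior = NULL, fdr = 0.2, source = "A") {
    m <- exprValues(bundle)
    grp <- cohortLabels(bundle)
    n1 <- sum(grp == 1); n2 <- sum(grp == 0)
    if (n1 < 2L || n2 < 2L)
        stop("each cohort needs at least 2 samples")
    x1 <- m[, grp == 1, drop = FALSE]
    x2 <- m[, grp == 0, drop = FALSE]
    mean1 <- rowMeans(x1); mean2 <- rowMeans(x2)
    lfc <- mean1 - mean2
    dg <- n1 + n2 - 2L
    s2g <- (rowSums((x1 - mean1)^2) + rowSums((x2 - mean2)^2)) / dg

    if (is.null(prior)) prior <- estimateModerationPrior(s2g, dg)
    d0 <- prior$d0; s02 <- prior$s02
    if (d0 < 0 || s02 <= 0) stop("invalid moderation prior")

    s2post <- if (is.infinite(d0)) rep(s02, length(s2g)) else
        (d0 * s02 + dg * s2g) / (d0 + dg)
    se <- sqrt(s2post * (1 / n1 + 1 / n2))
    tstat <- lfc / se          # 0/0 -> NaN for zero-variance, zero-LFC genes
    tstat[lfc == 0] <- 0
    tstat[lfc != 0 & se == 0] <- NA   # undefined: no variance information
    dfTotal <- d0 + dg
    p <- if (is.infinite(dfTotal)) 2 * pnorm(-abs(tstat)) else
        2 * pt(-abs(tstat), dfTotal)
    q <- adjustBH(p)
    tab <- data.frame(gene = rownames(m), lfc = lfc, t = tstat, p = p,
                      q = q, significant = !is.na(q) & q < fdr,
                      source = source, row.names = NULL,
                      stringsAsFactors = FALSE)
    methods::new("DEResult", table = tab,
                 prior = list(d0 = d0, s02 = s02), fdr = fdr)
}

#' Estimate the variance-moderation prior by moment matching
#'
#' Under the hierarchical model s2_g ~ s0^2 * F(d_g, d0), log s2_g has
#' known mean and variance in terms of digamma/trigamma functions. The
#' excess variance of log s2_g over trigamma(d_g/2) identifies d0 through
#' the inverse trigamma; the mean then identifies s0^2. Non-positive excess
#' variance gives d0 = Inf (all genes share one variance).
#'
#' @param s2g vector of gene-wise residual variances.
#' @param dg residual degrees of freedom (scalar).
#' @return list with `d0` and `s02`.
#' @export
estimateModerationPrior <- function(s2g, dg) {
    ok <- s2g > 0
    if (sum(ok) < 2L) stop("need at least 2 positive gene variances")
    z <- log(s2g[ok])
    e <- z - digamma(dg / 2) + log(dg / 2)
    ebar <- mean(e)
    evar <- var(e) - trigamma(dg / 2)
    if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s02 <- exp(ebar)
    } else {
        d0 <- 2 * .trigammaInverse(evar)
        s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    }
    list(d0 = d0, s02 = s02)
}

# Newton solve trigamma(y) = x on y > 0 (monotone decreasing, convex)
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-10) break
    }
    y
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validated wrapper around the standard step-up procedure:
#' q_(i) = min over j >= i of m p_(j) / j, clipped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted q-values.
#' @export
adjustBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Merge differential-expression results from two annotation definitions
#'
#' Takes the union of genes from two [DEResult-class] objects keyed by gene
#' symbol; a gene present in both keeps the entry with the smaller p
#' (ties: smaller q, then source A before B). Significance is re-evaluated
#' per kept entry at the gate, not re-adjusted across the merged list.
#' Genes whose two entries disagree on LFC sign are kept but listed in a
#' discordance report.
#'
#' @param resA,resB [DEResult-class] objects keyed by gene symbol.
#' @param fdr significance gate for the merged list (default: resA's gate).
#' @return a [DEResult-class]; the discordance report is in
#'   `attr(deTable(result), "discordant")`.
#' @export
mergeAnnotations <- function(resA, resB, fdr = NULL) {
    if (is.null(fdr)) fdr <- resA@fdr
    a <- deTable(resA); b <- deTable(resB)
    both <- intersect(a$gene, b$gene)
    discordant <- both[sign(a$lfc[match(both, a$gene)]) !=
                       sign(b$lfc[match(both, b$gene)])]
    comb <- rbind(a, b)
    # order: gene, then ascending p, q, source -> first row per gene wins
    ord <- order(comb$gene, comb$p, comb$q, comb$source, method = "radix")
    comb <- comb[ord, , drop = FALSE]
    out <- comb[!duplicated(comb$gene), , drop = FALSE]
    out$significant <- !is.na(out$q) & out$q < fdr
    rownames(out) <- NULL
    attr(out, "discordant") <- discordant
    methods::new("DEResult", table = out, prior = list(
        d0 = NA_real_, s02 = NA_real_), fdr = fdr)
}
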