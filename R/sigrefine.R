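#' Pairwise Spearman correlation with p-values
#'
#' Spearman's rho over all samples for the requested genes (ties
#' mid-ranked), with two-sided p-values from the t approximation
#' t = rho sqrt((n - 2) / (1 - rho^2)). Genes absent from the bundle are
#' dropped with a report; constant genes yield NA correlations.
#'
#' @param bundle an [ExpressionBundle-class] with >= 4 samples.
#' @param genes character vector of gene ids.
#' @return list with `rho`, `p` (square matrices) and `dropped`.
#' @export
spearmanMatrix <- function(bundle, genes) {
    m <- exprValues(bundle)
    if (ncol(m) < 4L) stop("need at least 4 samples")
    dropped <- setdiff(genes, rownames(m))
    genes <- intersect(genes, rownames(m))
    x <- m[genes, , drop = FALSE]
    constant <- apply(x, 1L, sd) == 0
    rho <- suppressWarnings(cor(t(x), method = "spearman"))
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
    n <- ncol(x)
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    p[abs(rho) >= 1 - 1e-12] <- 0
    p[is.na(rho)] <- NA_real_
    diag(p) <- 0
    list(rho = rho, p = p, dropped = dropped)
}

#' Two-pass co-expression refinement of a literature gene signature
#'
#' Pass 1 keeps gene g when it correlates significantly (p < alpha, gene
#' itself excluded) with at least a fraction `f` of the original signature
#' (count threshold ceiling(f (|signature| - 1))). Pass 2 keeps g when its
#' Spearman rho is positive with at least a fraction `f` of the pass-1 set
#' (again excluding itself). The refined set is always a subset of the
#' input; a full per-gene audit trail of the counts at each pass is
#' returned.
#'
#' @param bundle an [ExpressionBundle-class].
#' @param signature character vector of gene ids (>= 4 present in the
#'   bundle).
#' @param f fraction threshold (default 0.25).
#' @param alpha pass-1 significance level (default 0.05, two-sided).
#' @return list with `refined` (character vector), `audit` (data.frame of
#'   per-gene counts and keep flags per pass), `dropped` (absent genes).
#' @export
refineSignature <- function(bundle, signature, f = 0.25, alpha = 0.05) {
    if (f <= 0 || f > 1) stop("f must be in (0, 1]")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    sm <- spearmanMatrix(bundle, signature)
    genes <- rownames(sm$rho)
    if (length(genes) < 4L)
        stop("need at least 4 signature genes present in the matrix")
    k <- length(genes)
    need1 <- ceiling(f * (k - 1))
    sig <- !is.na(sm$p) & sm$p < alpha
    diag(sig) <- FALSE
    count1 <- rowSums(sig)
    keep1 <- count1 >= need1
    pass1 <- genes[keep1]
    if (!length(pass1)) {
        audit <- data.frame(gene = genes, pass1Count = count1,
                            pass1Need = need1, pass1Keep = keep1)
        stop("pass 1 removed every gene; audit trail:\n",
             paste(utils::capture.output(print(audit)), collapse = "\n"))
    }
    need2 <- ceiling(f * (length(pass1) - 1))
    pos <- !is.na(sm$rho) & sm$rho > 0
    diag(pos) <- FALSE
    # self-correlation already excluded through the zeroed diagonal
    count2 <- rowSums(pos[genes, pass1, drop = FALSE])
    keep2 <- keep1 & count2 >= need2
    audit <- data.frame(gene = genes, pass1Count = count1,
                        pass1Need = need1, pass1Keep = keep1,
                        pass2Count = count2, pass2Need = need2,
                        pass2Keep = keep2, row.names = NULL)
    list(refined = genes[keep2], audit = audit, dropped = sm$dropped)
}

#' Map a gene signature through an ortholog table
#'
#' Translates (e.g. mouse) symbols to target symbols through a
#' user-supplied two-column table; one-to-many mappings expand to all
#' targets and unmapped genes are reported, never silently dropped.
#'
#' @param signature character vector of source symbols.
#' @param orthologTable data.frame with columns `source`, `target` (extra
#'   columns ignored; first two used if unnamed).
#' @return list with `mapped` (character vector), `unmapped`, `expanded`
#'   (sources that mapped to more than one target).
#' @export
mapOrthologs <- function(signature, orthologTable) {
    tab <- as.data.frame(orthologTable)
    if (!nrow(tab)) stop("empty ortholog table")
    if (!all(c("source", "target") %in% colnames(tab)))
        colnames(tab)[1:2] <- c("source", "target")
    hits <- tab[tab$source %in% signature, c("source", "target")]
    mapped <- unique(hits$target)
    unmapped <- setdiff(signature, hits$source)
    expanded <- names(which(table(unique(hits)$source) > 1L))
    list(mapped = mapped, unmapped = unmapped, expanded = expanded)
}
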