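# fixtures built in code, shared across test files

makeBundle <- function(m, cohort = NULL, ...) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    if (is.null(cohort)) cohort <- rep(c(1, 0), length.out = ncol(m))
    ExpressionBundle(m, cohort, ...)
}

randomBundle <- function(nGenes = 30, n1 = 4, n2 = 4, seed = 1, sd = 1) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * (n1 + n2), 7, sd), nGenes)
    makeBundle(m, cohort = rep(c(1, 0), c(n1, n2)))
}

# ---- independent oracles -------------------------------------------------

# hypergeometric right tail P(X >= a) by direct log-binomial enumeration
oracleHyperTail <- function(a, b, c, d) {
    N <- a + b + c + d; K <- a + c; n <- a + b
    hi <- min(K, n)
    if (a > hi) return(0)
    terms <- vapply(a:hi, function(x)
        exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)),
        numeric(1))
    sum(terms)
}

# TOM by explicit triple loop over the formula
oracleTOM <- function(adj) {
    p <- nrow(adj)
    a <- adj; diag(a) <- 0
    k <- colSums(a)
    tom <- diag(p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
        tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
    dimnames(tom) <- dimnames(adj)
    tom
}

# KS random walk by explicit stepping
oracleWalk <- function(inSetOrdered, weightsOrdered, tau, mode = "diff") {
    p <- length(inSetOrdered)
    w <- weightsOrdered[inSetOrdered]^tau
    v <- 0; path <- numeric(p)
    for (i in seq_len(p)) {
        v <- v + if (inSetOrdered[i]) weightsOrdered[i]^tau / sum(w) else
            -1 / (p - sum(inSetOrdered))
        path[i] <- v
    }
    if (mode == "diff") max(0, max(path)) + min(0, min(path)) else
        path[which.max(abs(path))]
}

# two-pass refinement applied rule by rule from the rho/p matrices
oracleRefine <- function(rho, p, f, alpha) {
    genes <- rownames(rho)
    k <- length(genes)
    keep1 <- vapply(genes, function(g) {
        others <- setdiff(genes, g)
        sum(p[g, others] < alpha, na.rm = TRUE) >= ceiling(f * (k - 1))
    }, logical(1))
    pass1 <- genes[keep1]
    keep2 <- vapply(genes, function(g) {
        ref <- setdiff(pass1, g)
        sum(rho[g, ref] > 0, na.rm = TRUE) >=
            ceiling(f * (length(pass1) - 1))
    }, logical(1))
    genes[keep1 & keep2]
}

# BH decision rule: reject the smallest k p-values where k is the largest
# rank with p_(k) <= k alpha / m
oracleBHReject <- function(p, alpha) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    k <- max(c(0, which(ps <= seq_len(m) * alpha / m)))
    rej <- rep(FALSE, m)
    if (k > 0) rej[ord[seq_len(k)]] <- TRUE
    rej
}

# pooled two-sample t computed from first principles
oraclePooledT <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}
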