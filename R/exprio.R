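#' Read a log2 expression matrix into an ExpressionBundle
#'
#' Expects genes in rows with a leading gene-id column and one column per
#' sample. Malformed headers, non-numeric cells and duplicate sample ids
#' are rejected with a message naming the offending row/column.
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"`.
#' @param cohort binary cohort vector or NULL if supplied via `clinical`.
#' @param clinical optional clinical data.frame or path to a clinical CSV
#'   (must contain a `cohort` column when `cohort` is NULL).
#' @return an [ExpressionBundle-class].
#' @export
readExpression <- function(path, format = c("tsv", "csv"), cohort = NULL,
                           clinical = NULL) {
    format <- match.arg(format)
    sep <- if (format == "tsv") "\t" else ","
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    samples <- header[-1]
    if (anyDuplicated(samples))
        stop("duplicate sample id in header: ",
             samples[duplicated(samples)][1])
    raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    geneIds <- as.character(raw[[1]])
    if (anyDuplicated(geneIds))
        stop("duplicate gene id: ", geneIds[duplicated(geneIds)][1])
    m <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
        stop("non-numeric values in sample column '", samples[bad], "'")
    }
    dimnames(m) <- list(geneIds, samples)
    if (anyNA(m)) {
        idx <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop("missing value at gene '", geneIds[idx[1]], "', sample '",
             samples[idx[2]], "'")
    }
    if (is.character(clinical)) clinical <- readClinical(clinical)
    if (is.null(cohort)) {
        if (is.null(clinical) || !"cohort" %in% colnames(clinical))
            stop("cohort labels required (argument or clinical table)")
        ord <- if ("sample" %in% colnames(clinical)) {
            match(samples, clinical$sample)
        } else match(samples, rownames(clinical))
        cohort <- clinical$cohort[ord]
        clinical <- clinical[ord, setdiff(colnames(clinical), "cohort"),
                             drop = FALSE]
        if (!"sample" %in% colnames(clinical)) clinical$sample <- samples
    }
    if (!is.null(clinical) && ncol(clinical) <= 1L) clinical <- NULL
    ExpressionBundle(m, cohort, clinical = clinical)
}

#' Write an ExpressionBundle's matrix to TSV/CSV
#' @param bundle an [ExpressionBundle-class].
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
writeExpression <- function(bundle, path, format = c("tsv", "csv")) {
    format <- match.arg(format)
    sep <- if (format == "tsv") "\t" else ","
    m <- exprValues(bundle)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a per-sample clinical table (CSV)
#' @param path CSV with a `sample` column plus trait columns.
#' @return data.frame.
#' @export
readClinical <- function(path) {
    read.delim(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes...
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1], ": need name, description, ",
             "and at least one gene")
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description single description string or vector per set.
#' @export
writeGMT <- function(sets, path, description = "na") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Remove low-intensity / low-variability genes
#'
#' Two modes used at different pipeline stages: `"threshold"` removes genes
#' whose maximum log2 intensity across samples falls below an absolute
#' cutoff (default 2.34, the low-intensity floor for log2 array data;
#' a gene is kept if *any* sample exceeds the cutoff), and `"iqr"` removes
#' genes whose interquartile range falls below a given quantile of the
#' per-gene IQR distribution (pre-filter for per-sample gene-set scoring).
#'
#' @param bundle an [ExpressionBundle-class].
#' @param method `"threshold"` or `"iqr"`.
#' @param threshold absolute log2 cutoff (threshold mode).
#' @param iqrQuantile quantile of per-gene IQRs in (0,1) below which genes
#'   are dropped (iqr mode).
#' @return the filtered bundle; the number and ids of removed genes are in
#'   `metadata(bundle)$filterReport`.
#' @export
filterLowIntensity <- function(bundle, method = c("threshold", "iqr"),
                               threshold = 2.34, iqrQuantile = 0.5) {
    method <- match.arg(method)
    m <- exprValues(bundle)
    if (method == "threshold") {
        keep <- apply(m, 1L, max) >= threshold
    } else {
        if (iqrQuantile <= 0 || iqrQuantile >= 1)
            stop("iqrQuantile must be in (0, 1)")
        iqr <- apply(m, 1L, function(x)
            diff(quantile(x, c(0.25, 0.75), names = FALSE)))
        keep <- iqr >= quantile(iqr, iqrQuantile, names = FALSE)
    }
    if (!any(keep))
        stop("filter removed every gene (degenerate matrix)")
    out <- .subsetGenes(bundle, which(keep))
    rep0 <- S4Vectors::metadata(out)$filterReport
    S4Vectors::metadata(out)$filterReport <- c(rep0, list(list(
        method = method,
        cutoff = if (method == "threshold") threshold else iqrQuantile,
        removed = sum(!keep), removedGenes = rownames(m)[!keep])))
    out
}

#' Flag outlier samples by principal components and dendrogram position
#'
#' Automates the visual outlier screen used for small array cohorts: a
#' sample is flagged when (i) its distance from its cohort centroid in
#' PC1-PC3 space exceeds `k` times the MAD of all such distances, and (ii)
#' it joins the Euclidean-distance UPGMA (average-linkage) dendrogram last,
#' at a height exceeding 1.5x the previous merge. Both sub-criteria are
#' reported separately in the diagnostics; the flag is their conjunction.
#'
#' @param bundle an [ExpressionBundle-class] with >= 4 samples.
#' @param k MAD multiplier for the PC-distance rule (default 3).
#' @return list with `flagged` (sample ids), `pcDistance`, `pcFlag`,
#'   `dendroFlag`, `pcCoords`, `mergeHeights`.
#' @export
detectOutlierSamples <- function(bundle, k = 3) {
    m <- exprValues(bundle)
    if (ncol(m) < 4L) stop("insufficient samples (need >= 4)")
    cohort <- cohortLabels(bundle)
    pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
    npc <- min(3L, ncol(pc$x))
    coords <- pc$x[, seq_len(npc), drop = FALSE]
    dists <- vapply(seq_len(ncol(m)), function(i) {
        same <- which(cohort == cohort[i])
        others <- setdiff(same, i)
        centroid <- if (length(others))
            colMeans(coords[others, , drop = FALSE]) else
            colMeans(coords[same, , drop = FALSE])
        sqrt(sum((coords[i, ] - centroid)^2))
    }, numeric(1))
    names(dists) <- colnames(m)
    scale0 <- mad(dists)
    pcFlag <- if (scale0 == 0) rep(FALSE, length(dists)) else
        dists > k * scale0

    hc <- hclust(dist(t(m)), method = "average")
    heights <- hc$height
    nm <- length(heights)
    # leaf that enters the tree at the final merge, if it is a singleton
    dendroFlag <- rep(FALSE, ncol(m))
    names(dendroFlag) <- colnames(m)
    last <- hc$merge[nm, ]
    lateLeaves <- -last[last < 0]
    if (length(lateLeaves) && nm >= 2L && heights[nm] > 1.5 * heights[nm - 1L])
        dendroFlag[lateLeaves] <- TRUE
    flag <- pcFlag & dendroFlag
    list(flagged = colnames(m)[flag], pcDistance = dists, pcFlag = pcFlag,
         dendroFlag = dendroFlag, pcCoords = coords,
         mergeHeights = heights)
}

#' Collapse probe-level rows to one row per gene
#'
#' Generic over the object being collapsed: for an expression bundle the
#' rule is `"max_mean"` (keep the probe with the highest mean intensity) or
#' `"max_kME"` (keep the probe with the strongest within-module correlation
#' to its module eigengene; requires `moduleSet`); for a differential
#' expression result the rule is `"min_p"` (keep the most significant
#' probe). Ties are broken lexicographically by probe id.
#'
#' @param x an [ExpressionBundle-class] or [DEResult-class].
#' @param probeMap data.frame with columns `probe`, `gene`; must cover
#'   every row of `x`.
#' @param rule collapse rule (see above).
#' @param moduleSet a [ModuleSet-class], required for `rule = "max_kME"`.
#' @return object of the same class with unique gene rows.
#' @export
setGeneric("collapseProbes", function(x, probeMap, rule, moduleSet = NULL)
    standardGeneric("collapseProbes"))

.checkProbeMap <- function(ids, probeMap) {
    if (!all(c("probe", "gene") %in% colnames(probeMap)))
        stop("probeMap needs columns 'probe' and 'gene'")
    miss <- setdiff(ids, probeMap$probe)
    if (length(miss))
        stop("probeMap does not cover probe(s): ",
             paste(head(miss, 3L), collapse = ", "))
    stats::setNames(as.character(probeMap$gene),
                    as.character(probeMap$probe))[ids]
}

# pick, within each gene, the probe maximizing `score`; ties lexicographic
.pickProbes <- function(probes, genes, score) {
    ord <- order(genes, -score, probes, method = "radix")
    keep <- ord[!duplicated(genes[ord])]
    sort(keep)
}

#' @rdname collapseProbes
setMethod("collapseProbes", "ExpressionBundle",
    function(x, probeMap, rule = c("max_mean", "max_kME"),
             moduleSet = NULL) {
    rule <- match.arg(rule)
    genes <- .checkProbeMap(rownames(x), probeMap)
    m <- exprValues(x)
    score <- if (rule == "max_mean") {
        rowMeans(m)
    } else {
        if (is.null(moduleSet))
            stop("rule 'max_kME' requires a ModuleSet")
        kme <- moduleMembership(moduleSet)
        lab <- moduleLabels(moduleSet)[rownames(x)]
        vapply(seq_len(nrow(m)), function(i) {
            if (is.na(lab[i]) || lab[i] == "grey" ||
                !lab[i] %in% colnames(kme)) -Inf
            else kme[rownames(m)[i], lab[i]]
        }, numeric(1))
    }
    keep <- .pickProbes(rownames(m), genes, score)
    out <- .subsetGenes(x, keep)
    rownames(out) <- genes[keep]
    out
})

#' @rdname collapseProbes
setMethod("collapseProbes", "DEResult",
    function(x, probeMap, rule = "min_p", moduleSet = NULL) {
    if (!identical(rule, "min_p"))
        stop("DEResult collapse supports rule 'min_p' only")
    tab <- deTable(x)
    genes <- .checkProbeMap(tab$gene, probeMap)
    keep <- .pickProbes(tab$gene, genes, -tab$p)
    tab <- tab[keep, , drop = FALSE]
    tab$gene <- genes[keep]
    rownames(tab) <- NULL
    methods::new("DEResult", table = tab, prior = x@prior, fdr = x@fdr)
})
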