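#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor cor.test mad p.adjust pnorm prcomp pt phyper
#'   qnorm quantile rnorm runif sd setNames var hclust cutree as.dist
#'   dist median aggregate complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Container for a log2 expression matrix with cohort labels and clinical data
#'
#' `ExpressionBundle` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with the conventions
#' used throughout this package: a single `"exprs"` assay of log2 intensity
#' values (genes in rows, samples in columns), a mandatory binary `cohort`
#' column in `colData` (case = 1, control = 0), optional clinical trait
#' columns, and, for synthetic data, a ground-truth record in `metadata()`.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("ExpressionBundle", contains = "SummarizedExperiment")

setValidity("ExpressionBundle", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(m))
            msg <- c(msg, "assay 'exprs' must be numeric")
        if (anyNA(m))
            msg <- c(msg, "assay 'exprs' must not contain missing values")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!"cohort" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'cohort' column")
    else {
        ch <- SummarizedExperiment::colData(object)$cohort
        if (!all(ch %in% c(0, 1)))
            msg <- c(msg, "cohort labels must be 0 (control) or 1 (case)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionBundle
#'
#' @param exprs numeric matrix of log2 intensities, genes in rows (unique
#'   rownames), samples in columns (unique colnames).
#' @param cohort binary vector (1 = case, 0 = control), one per sample.
#' @param clinical optional data.frame of clinical traits, one row per sample
#'   (rownames or a `sample` column matching `colnames(exprs)`).
#' @param probeMap optional data.frame with columns `probe`, `gene` mapping
#'   rownames to gene symbols.
#' @param groundTruth optional list recording planted structure (synthetic
#'   data only).
#' @return an [ExpressionBundle-class] object.
#' @export
ExpressionBundle <- function(exprs, cohort, clinical = NULL, probeMap = NULL,
                             groundTruth = NULL) {
    exprs <- as.matrix(exprs)
    if (length(cohort) != ncol(exprs))
        stop("'cohort' must have one entry per sample column")
    cd <- S4Vectors::DataFrame(cohort = as.numeric(cohort),
                               row.names = colnames(exprs))
    if (!is.null(clinical)) {
        clinical <- as.data.frame(clinical)
        if ("sample" %in% colnames(clinical)) {
            rownames(clinical) <- clinical$sample
            clinical$sample <- NULL
        }
        if (!all(colnames(exprs) %in% rownames(clinical)))
            stop("clinical table must cover every sample id")
        clinical <- clinical[colnames(exprs), , drop = FALSE]
        bad <- vapply(clinical, function(x)
            is.numeric(x) && any(x < 0, na.rm = TRUE), logical(1))
        if (any(bad))
            stop("clinical numeric fields must be nonnegative: ",
                 paste(names(bad)[bad], collapse = ", "))
        for (nm in colnames(clinical)) cd[[nm]] <- clinical[[nm]]
    }
    md <- list()
    if (!is.null(probeMap)) md$probeMap <- probeMap
    if (!is.null(groundTruth)) md$groundTruth <- groundTruth
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd, metadata = md)
    methods::new("ExpressionBundle", se)
}

#' Result container for moderated differential expression
#'
#' Holds the per-gene table (log2 fold change, moderated t, p, BH q,
#' significance flag, annotation source) together with the empirical-Bayes
#' moderation prior that produced it.
#'
#' @slot table data.frame with columns gene, lfc, t, p, q, significant,
#'   source.
#' @slot prior list with elements `d0` (prior degrees of freedom) and `s02`
#'   (prior variance).
#' @slot fdr numeric FDR gate used for the significance flag.
#' @export
setClass("DEResult",
    representation(table = "data.frame", prior = "list", fdr = "numeric"))

setValidity("DEResult", function(object) {
    need <- c("gene", "lfc", "t", "p", "q", "significant", "source")
    if (!all(need %in% colnames(object@table)))
        return(paste("table must contain columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(object@table$gene))
        return("gene ids must be unique")
    TRUE
})

#' Co-expression module set
#'
#' Gene-to-module assignment plus module eigengenes (ME), eigengene-based
#' connectivity (kME), module-trait correlations and QC metrics. The label
#' `"grey"` denotes unassigned genes.
#'
#' @slot labels named character vector, gene -> module label.
#' @slot ME numeric matrix, samples x modules, each column the first
#'   principal component of the module's standardized expression
#'   (unit-norm, sign-fixed to correlate positively with the module mean
#'   profile).
#' @slot kME numeric matrix, genes x modules, Pearson correlation of each
#'   gene with each ME.
#' @slot traitCor data.frame of module-trait Pearson correlations (may be
#'   empty before [correlateTraits()]).
#' @slot params list of network parameters used.
#' @slot qc list of QC metrics (filled by [qcModule()]).
#' @export
setClass("ModuleSet",
    representation(labels = "character", ME = "matrix", kME = "matrix",
                   traitCor = "data.frame", params = "list", qc = "list"))

setValidity("ModuleSet", function(object) {
    if (is.null(names(object@labels)))
        return("labels must be named by gene id")
    if (length(object@kME) && any(abs(object@kME) > 1 + 1e-8, na.rm = TRUE))
        return("|kME| must not exceed 1")
    TRUE
})

setMethod("show", "ExpressionBundle", function(object) {
    cat("ExpressionBundle:", nrow(object), "genes x", ncol(object),
        "samples\n")
    ch <- SummarizedExperiment::colData(object)$cohort
    cat("  cohort: ", sum(ch == 1), " case / ", sum(ch == 0), " control\n",
        sep = "")
    extra <- setdiff(colnames(SummarizedExperiment::colData(object)),
                     "cohort")
    if (length(extra))
        cat("  clinical traits:", paste(extra, collapse = ", "), "\n")
    if (!is.null(S4Vectors::metadata(object)$groundTruth))
        cat("  synthetic: ground truth attached\n")
})

setMethod("show", "DEResult", function(object) {
    cat("DEResult:", nrow(object@table), "genes;",
        sum(object@table$significant), "significant at q <", object@fdr, "\n")
    cat("  prior: d0 =", format(object@prior$d0),
        " s0^2 =", format(object@prior$s02), "\n")
})

setMethod("show", "ModuleSet", function(object) {
    tab <- table(object@labels)
    tab <- tab[order(-tab)]
    cat("ModuleSet:", length(object@labels), "genes in",
        sum(names(tab) != "grey"), "modules\n")
    print(tab)
})
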