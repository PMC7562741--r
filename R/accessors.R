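#' Accessors for package classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param object an [ExpressionBundle-class], [DEResult-class] or
#'   [ModuleSet-class].
#' @name accessors
NULL

#' @describeIn accessors log2 intensity matrix (genes x samples).
#' @export
exprValues <- function(object) {
    stopifnot(methods::is(object, "ExpressionBundle"))
    SummarizedExperiment::assay(object, "exprs")
}

#' @describeIn accessors binary cohort labels (1 = case, 0 = control).
#' @export
cohortLabels <- function(object) {
    stopifnot(methods::is(object, "ExpressionBundle"))
    stats::setNames(SummarizedExperiment::colData(object)$cohort,
                    colnames(object))
}

#' @describeIn accessors clinical trait data.frame (may have zero columns).
#' @export
clinicalData <- function(object) {
    stopifnot(methods::is(object, "ExpressionBundle"))
    cd <- SummarizedExperiment::colData(object)
    as.data.frame(cd[, setdiff(colnames(cd), "cohort"), drop = FALSE])
}

#' @describeIn accessors ground-truth record of a synthetic bundle
#'   (NULL for real data).
#' @export
groundTruth <- function(object) {
    stopifnot(methods::is(object, "ExpressionBundle"))
    S4Vectors::metadata(object)$groundTruth
}

#' @describeIn accessors per-gene differential-expression table.
#' @export
deTable <- function(object) {
    stopifnot(methods::is(object, "DEResult"))
    object@table
}

#' @describeIn accessors empirical-Bayes prior (d0, s02) of a DEResult.
#' @export
dePrior <- function(object) {
    stopifnot(methods::is(object, "DEResult"))
    object@prior
}

#' @describeIn accessors gene -> module label vector.
#' @export
moduleLabels <- function(object) {
    stopifnot(methods::is(object, "ModuleSet"))
    object@labels
}

#' @describeIn accessors module eigengene matrix (samples x modules).
#' @export
moduleEigengenes <- function(object) {
    stopifnot(methods::is(object, "ModuleSet"))
    object@ME
}

#' @describeIn accessors kME matrix (genes x modules).
#' @export
moduleMembership <- function(object) {
    stopifnot(methods::is(object, "ModuleSet"))
    object@kME
}

#' @describeIn accessors module-trait correlation table.
#' @export
moduleTraitCor <- function(object) {
    stopifnot(methods::is(object, "ModuleSet"))
    object@traitCor
}

# internal: replace the expression matrix keeping metadata/colData
.replaceExprs <- function(bundle, m) {
    SummarizedExperiment::assay(bundle, "exprs") <- m
    bundle
}

# internal: subset genes of a bundle by row index/names, keeping class
.subsetGenes <- function(bundle, idx) {
    bundle[idx, ]
}
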