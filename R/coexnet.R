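#' Network parameters for co-expression module discovery
#'
#' @param power soft-thresholding exponent beta applied to the absolute (or
#'   signed-rescaled) correlation (default 30, suited to small-n array
#'   cohorts where correlations are inflated).
#' @param signed use the signed adjacency ((1 + cor)/2)^beta instead of
#'   |cor|^beta.
#' @param minSize minimum module size (default 100).
#' @param cutHeight static cut height on the 1 - TOM dendrogram (default
#'   0.9999; see the methods vignette for why the static cut needs a height
#'   strictly inside the dendrogram).
#' @param mergeHeight eigengene dissimilarity below which modules merge
#'   (default 0.2).
#' @param pam reassign dissolved/unassigned genes to the nearest module by
#'   mean TOM similarity (default TRUE).
#' @return validated list of class `"NetworkParams"`.
#' @export
networkParams <- function(power = 30, signed = FALSE, minSize = 100L,
                          cutHeight = 0.9999, mergeHeight = 0.2, pam = TRUE) {
    if (power < 1) stop("power must be >= 1")
    if (mergeHeight <= 0 || mergeHeight >= 1)
        stop("mergeHeight must be in (0, 1)")
    if (minSize < 3L) stop("minSize must be >= 3")
    structure(list(power = power, signed = signed,
                   minSize = as.integer(minSize), cutHeight = cutHeight,
                   mergeHeight = mergeHeight, pam = pam),
              class = "NetworkParams")
}

#' Topological overlap matrix from soft-thresholded adjacency
#'
#' Computes the correlation-based adjacency a_ij = |cor(x_i, x_j)|^beta
#' (unsigned default) and the topological overlap
#' \deqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) /
#'   (\min(k_i, k_j) + 1 - a_{ij})}
#' with unit diagonal, where k_i is the connectivity sum over u != i. TOM
#' is symmetric with values in [0, 1].
#'
#' @param x an [ExpressionBundle-class] or a genes-x-samples numeric
#'   matrix; genes with zero variance must be removed first.
#' @param params a [networkParams()] object.
#' @return symmetric TOM matrix (genes x genes).
#' @export
buildTOM <- function(x, params = networkParams()) {
    m <- if (methods::is(x, "ExpressionBundle")) exprValues(x) else x
    if (ncol(m) < 4L) stop("need at least 4 samples")
    v <- apply(m, 1L, var)
    if (any(v == 0))
        stop("zero-variance gene present: ", rownames(m)[which(v == 0)[1]])
    cr <- cor(t(m))
    a <- if (params$signed) ((1 + cr) / 2)^params$power else
        abs(cr)^params$power
    .tomFromAdjacency(a)
}

# TOM from an adjacency matrix with unit diagonal
.tomFromAdjacency <- function(a) {
    diag(a) <- 0
    k <- colSums(a)
    num <- a %*% a + a
    denom <- outer(k, k, pmin) + 1 - a
    tom <- num / denom
    diag(tom) <- 1
    dimnames(tom) <- dimnames(a)
    tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut statically at `cutHeight`; clusters smaller than `minSize` are
#' dissolved to the unassigned pool ("grey"). A partitioning-around-medoids
#' style pass then reassigns each unassigned gene to the module with the
#' highest mean TOM similarity, provided that similarity exceeds the gene's
#' mean similarity to the remaining grey background. Modules are labelled
#' from a fixed palette in decreasing size order, so labels are
#' deterministic.
#'
#' @param tom TOM matrix from [buildTOM()].
#' @param params a [networkParams()] object.
#' @return a [ModuleSet-class] (labels only; eigengenes via
#'   [computeEigengenes()]).
#' @export
detectModules <- function(tom, params = networkParams()) {
    genes <- rownames(tom)
    hc <- hclust(as.dist(1 - tom), method = "average")
    cl <- cutree(hc, h = params$cutHeight)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= params$minSize]
    lab <- ifelse(cl %in% as.integer(keep), as.character(cl), "grey")
    names(lab) <- genes
    if (all(lab == "grey"))
        warning("no module reached the minimum size; all genes grey")
    if (params$pam && any(lab == "grey") && any(lab != "grey")) {
        mods <- unique(lab[lab != "grey"])
        greyIdx <- which(lab == "grey")
        meanSim <- vapply(mods, function(md)
            rowMeans(tom[greyIdx, lab == md, drop = FALSE]),
            numeric(length(greyIdx)))
        meanSim <- matrix(meanSim, nrow = length(greyIdx),
                          dimnames = list(genes[greyIdx], mods))
        greySim <- if (length(greyIdx) > 1L)
            (rowSums(tom[greyIdx, greyIdx, drop = FALSE]) - 1) /
                (length(greyIdx) - 1L) else rep(0, length(greyIdx))
        best <- max.col(meanSim, ties.method = "first")
        bestVal <- meanSim[cbind(seq_along(greyIdx), best)]
        move <- bestVal > greySim
        lab[greyIdx[move]] <- mods[best[move]]
    }
    methods::new("ModuleSet", labels = .colorLabels(lab),
                 ME = matrix(numeric(0), 0, 0),
                 kME = matrix(numeric(0), 0, 0),
                 traitCor = data.frame(), params = unclass(params),
                 qc = list())
}

# deterministic palette, assigned in decreasing module-size order
.modulePalette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan")

.colorLabels <- function(lab) {
    mods <- setdiff(names(sort(table(lab), decreasing = TRUE)), "grey")
    pal <- c(.modulePalette,
             sprintf("module%03d", seq_len(max(0, length(mods) -
                                               length(.modulePalette)))))
    map <- stats::setNames(pal[seq_along(mods)], mods)
    out <- ifelse(lab == "grey", "grey", map[lab])
    names(out) <- names(lab)
    out
}

#' Module eigengenes and eigengene-based connectivity (kME)
#'
#' The module eigengene (ME) is the first principal component of the
#' module's standardized (per-gene z-scored) expression, unit-norm across
#' samples, sign-fixed so it correlates positively with the module's mean
#' standardized profile. kME is the Pearson correlation of every gene in
#' the bundle with every ME.
#'
#' @param bundle an [ExpressionBundle-class].
#' @param moduleSet a [ModuleSet-class] with labels covering the bundle's
#'   genes.
#' @return the moduleSet with `ME`, `kME` and per-module explained
#'   variance (in `@qc$varExplained`) filled in.
#' @export
computeEigengenes <- function(bundle, moduleSet) {
    m <- exprValues(bundle)
    lab <- moduleLabels(moduleSet)[rownames(m)]
    mods <- setdiff(unique(lab[!is.na(lab)]), "grey")
    if (!length(mods)) stop("no modules to summarize")
    mods <- mods[order(mods)]
    ME <- matrix(NA_real_, ncol(m), length(mods),
                 dimnames = list(colnames(m), mods))
    varExpl <- stats::setNames(numeric(length(mods)), mods)
    for (md in mods) {
        sub <- m[which(lab == md), , drop = FALSE]
        if (nrow(sub) == 1L)
            warning("module '", md, "' has a single gene; ME is its ",
                    "standardized profile")
        z <- t(scale(t(sub)))
        sv <- svd(z)
        me <- sv$v[, 1]
        if (cor(me, colMeans(z)) < 0) me <- -me
        ME[, md] <- me
        varExpl[md] <- sv$d[1]^2 / sum(sv$d^2)
    }
    kME <- cor(t(m), ME)
    moduleSet@ME <- ME
    moduleSet@kME <- kME
    moduleSet@qc$varExplained <- varExpl
    methods::validObject(moduleSet)
    moduleSet
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengene dissimilarity 1 - cor(ME_a, ME_b) falls below
#' the merge height are merged (complete linkage over the ME dendrogram),
#' eigengenes are recomputed, and the step repeats until stable.
#'
#' @param bundle an [ExpressionBundle-class].
#' @param moduleSet a [ModuleSet-class] with eigengenes computed.
#' @param mergeHeight dissimilarity threshold (default: the set's stored
#'   parameter, 0.2).
#' @return a [ModuleSet-class] with merged labels and fresh eigengenes.
#' @export
mergeModules <- function(bundle, moduleSet, mergeHeight = NULL) {
    if (is.null(mergeHeight))
        mergeHeight <- moduleSet@params$mergeHeight
    repeat {
        ME <- moduleEigengenes(moduleSet)
        if (ncol(ME) < 2L) break
        d <- 1 - cor(ME)
        hc <- hclust(as.dist(d), method = "complete")
        grp <- cutree(hc, h = mergeHeight)
        if (max(grp) == ncol(ME)) break
        lab <- moduleLabels(moduleSet)
        # merged group inherits the label of its largest member
        for (g in unique(grp)) {
            members <- names(grp)[grp == g]
            if (length(members) < 2L) next
            sizes <- table(lab)[members]
            tgt <- members[which.max(sizes)]
            lab[lab %in% members] <- tgt
        }
        moduleSet@labels <- lab
        moduleSet <- computeEigengenes(bundle, moduleSet)
    }
    moduleSet
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation (r and two-sided p) of each ME with each clinical
#' trait, cohort included as a binary 0/1 variable. Missing trait values
#' are handled by pairwise deletion and the effective n is reported; a
#' constant trait yields NA with a reason.
#'
#' @param moduleSet a [ModuleSet-class] with eigengenes.
#' @param bundle the [ExpressionBundle-class] carrying cohort and clinical
#'   columns.
#' @return the moduleSet with `@traitCor` filled (module, trait, r, p, n,
#'   note).
#' @export
correlateTraits <- function(moduleSet, bundle) {
    ME <- moduleEigengenes(moduleSet)
    traits <- cbind(cohort = cohortLabels(bundle), clinicalData(bundle))
    traits <- traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE]
    rows <- list()
    for (md in colnames(ME)) for (tr in colnames(traits)) {
        y <- traits[[tr]]
        ok <- !is.na(y)
        note <- ""
        if (sum(ok) < 3L || sd(y[ok]) == 0) {
            r <- NA_real_; p <- NA_real_
            note <- if (sum(ok) < 3L) "too few complete pairs" else
                "constant trait"
        } else {
            ct <- cor.test(ME[ok, md], y[ok], method = "pearson")
            r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
            module = md, trait = tr, r = r, p = p, n = sum(ok),
            note = note, stringsAsFactors = FALSE)
    }
    moduleSet@traitCor <- do.call(rbind, rows)
    moduleSet
}

#' Module quality control
#'
#' Three checks that a module reflects the biology it is meant to track:
#' (i) per-cohort ME consistency (cohort means and the fraction of samples
#' whose ME sign matches their cohort mean's sign); (ii) concordance of
#' module membership with trait relevance - the Pearson correlation, over
#' the module's genes, between kME and each gene's correlation with the
#' primary clinical trait; (iii) classification of each module-trait
#' correlation as "strong" when |r| lies in [0.5, 1] (boundary inclusive)
#' and p < alpha.
#'
#' @param moduleSet a [ModuleSet-class] with eigengenes and trait
#'   correlations.
#' @param bundle the [ExpressionBundle-class].
#' @param module module label to QC.
#' @param trait primary clinical trait name (default "SLEDAI").
#' @param alpha significance level for the strong/weak call (default 0.05).
#' @return list with `meByCohort`, `meSignConsistency`, `concordance`,
#'   `traitClassification`.
#' @export
qcModule <- function(moduleSet, bundle, module, trait = "SLEDAI",
                     alpha = 0.05) {
    ME <- moduleEigengenes(moduleSet)
    if (!module %in% colnames(ME)) stop("unknown module: ", module)
    me <- ME[, module]
    grp <- cohortLabels(bundle)
    meByCohort <- tapply(me, grp, mean)
    signCons <- mean(sign(me) == sign(meByCohort[as.character(grp)]))

    traits <- cbind(cohort = cohortLabels(bundle), clinicalData(bundle))
    concordance <- NA_real_
    if (trait %in% colnames(traits)) {
        y <- traits[[trait]]
        genes <- names(moduleLabels(moduleSet))[
            moduleLabels(moduleSet) == module]
        m <- exprValues(bundle)[genes, , drop = FALSE]
        geneTrait <- apply(m, 1L, function(x)
            if (sd(y) == 0) NA_real_ else cor(x, y))
        kme <- moduleMembership(moduleSet)[genes, module]
        if (length(genes) >= 3L && sd(geneTrait, na.rm = TRUE) > 0)
            concordance <- cor(kme, geneTrait, use = "complete.obs")
    }
    tc <- moduleTraitCor(moduleSet)
    tc <- tc[tc$module == module, , drop = FALSE]
    tc$strong <- !is.na(tc$r) & abs(tc$r) >= 0.5 & abs(tc$r) <= 1 &
        !is.na(tc$p) & tc$p < alpha
    list(meByCohort = meByCohort, meSignConsistency = signCons,
         concordance = concordance, traitClassification = tc)
}
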