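#' Simulation configuration for synthetic immunoprofiling data
#'
#' Builds and validates the configuration consumed by
#' [generateExpression()], [generateTaxonomy()] and
#' [generateConnectivityTable()]. Defaults emulate a small two-cohort
#' synovial microarray study: ~20,000 genes, 4 case vs 4 control samples,
#' planted cohort fold changes on immune-signature genes, and latent-factor
#' co-expression modules whose activity drives clinical traits.
#'
#' @param nGenes total number of genes.
#' @param nPerCohort integer pair: samples in (case, control).
#' @param nSignal number of genes with a planted cohort fold change.
#' @param lfcRange interval (log2 units) from which planted |LFC| magnitudes
#'   are drawn; must lie within [0.25, 5] unless both endpoints are 0
#'   (null case).
#' @param propUp proportion of signal genes up-regulated in cases.
#' @param nModules number of planted co-expression modules.
#' @param moduleSize genes per module.
#' @param factorNoiseSd residual Gaussian sd around the latent factor for
#'   module genes.
#' @param moduleLoadingRange interval from which per-gene factor loadings
#'   are drawn (positive).
#' @param baselineMean,baselineSd mean/sd of per-gene baseline log2
#'   intensity.
#' @param residualSd residual sd for non-module genes.
#' @param traitLoadings named numeric vector, module index ("1", "2", ...)
#'   -> loading of that module's latent factor on the primary clinical
#'   trait (SLEDAI).
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simConfig <- function(nGenes = 20000L, nPerCohort = c(4L, 4L),
                      nSignal = 500L, lfcRange = c(0.5, 2.5),
                      propUp = 0.5, nModules = 3L, moduleSize = 120L,
                      factorNoiseSd = 0.5, moduleLoadingRange = c(0.7, 1.3),
                      baselineMean = 7, baselineSd = 1.5, residualSd = 0.5,
                      traitLoadings = c("1" = 2), seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes),
                nPerCohort = as.integer(nPerCohort),
                nSignal = as.integer(nSignal), lfcRange = as.numeric(lfcRange),
                propUp = propUp, nModules = as.integer(nModules),
                moduleSize = as.integer(moduleSize),
                factorNoiseSd = factorNoiseSd,
                moduleLoadingRange = as.numeric(moduleLoadingRange),
                baselineMean = baselineMean, baselineSd = baselineSd,
                residualSd = residualSd, traitLoadings = traitLoadings,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    .validateSimConfig(cfg)
    cfg
}

.validateSimConfig <- function(cfg) {
    if (length(cfg$nPerCohort) != 2L || any(cfg$nPerCohort < 1L))
        stop("nPerCohort must be two positive counts")
    if (cfg$nSignal + cfg$nModules * cfg$moduleSize > cfg$nGenes)
        stop("nSignal + total module genes must not exceed nGenes")
    lr <- cfg$lfcRange
    if (length(lr) != 2L || lr[1] > lr[2])
        stop("lfcRange must be an interval c(lo, hi)")
    if (!(all(lr == 0)) && (lr[1] < 0.25 || lr[2] > 5))
        stop("lfcRange must lie within [0.25, 5] (or be c(0, 0))")
    if (cfg$factorNoiseSd < 0 || cfg$residualSd < 0 || cfg$baselineSd < 0)
        stop("noise standard deviations must be nonnegative")
    if (cfg$propUp < 0 || cfg$propUp > 1)
        stop("propUp must be in [0, 1]")
    if (any(cfg$moduleLoadingRange <= 0))
        stop("module loadings must be positive")
    invisible(cfg)
}

#' Generate a synthetic expression bundle with known ground truth
#'
#' Draws a log2 genes-x-samples matrix with three planted layers: (i)
#' cohort-differential "signal" genes whose case-vs-control mean shift
#' equals their recorded true LFC; (ii) co-expression modules generated as
#' gene loading x per-sample latent factor + Gaussian noise; (iii)
#' independent background genes. Clinical traits (SLEDAI, anti-dsDNA, C3,
#' C4, CRP) are linear functions of chosen latent factors plus noise, scaled
#' to realistic clinical units, so module-trait correlations have known
#' targets. The full generative record is attached as ground truth.
#'
#' @param config a [simConfig()] object.
#' @return an [ExpressionBundle-class] with `groundTruth()` attached.
#' @export
generateExpression <- function(config) {
    .validateSimConfig(config)
    set.seed(config$seed)
    n1 <- config$nPerCohort[1]; n2 <- config$nPerCohort[2]
    n <- n1 + n2
    G <- config$nGenes
    geneIds <- sprintf("G%05d", seq_len(G))
    sampleIds <- c(sprintf("CASE%02d", seq_len(n1)),
                   sprintf("CTRL%02d", seq_len(n2)))
    cohort <- c(rep(1, n1), rep(0, n2))

    baseline <- rnorm(G, config$baselineMean, config$baselineSd)
    x <- matrix(rnorm(G * n, 0, config$residualSd), G, n,
                dimnames = list(geneIds, sampleIds)) + baseline

    # planted cohort fold changes on the first nSignal genes
    signalIdx <- seq_len(config$nSignal)
    nUp <- round(config$propUp * config$nSignal)
    sign <- rep(c(1, -1), c(nUp, config$nSignal - nUp))
    mag <- runif(config$nSignal, config$lfcRange[1], config$lfcRange[2])
    trueLfc <- sign * mag
    if (config$nSignal > 0)
        x[signalIdx, cohort == 1] <- x[signalIdx, cohort == 1] + trueLfc

    # planted latent-factor modules after the signal block
    nMod <- config$nModules
    moduleGenes <- list()
    factors <- matrix(0, n, nMod,
                      dimnames = list(sampleIds,
                                      as.character(seq_len(nMod))))
    loadings <- numeric(0)
    if (nMod > 0) {
        factors[] <- rnorm(n * nMod)
        for (m in seq_len(nMod)) {
            idx <- config$nSignal + (m - 1) * config$moduleSize +
                seq_len(config$moduleSize)
            lam <- runif(config$moduleSize, config$moduleLoadingRange[1],
                         config$moduleLoadingRange[2])
            x[idx, ] <- baseline[idx] + outer(lam, factors[, m]) +
                matrix(rnorm(config$moduleSize * n, 0, config$factorNoiseSd),
                       ncol = n)
            moduleGenes[[as.character(m)]] <- geneIds[idx]
            loadings <- c(loadings, stats::setNames(lam, geneIds[idx]))
        }
    }

    clinical <- .generateTraits(config, factors, cohort)
    truth <- list(
        signalGenes = stats::setNames(trueLfc, geneIds[signalIdx]),
        moduleGenes = moduleGenes,
        moduleLoadings = loadings,
        latentFactors = factors,
        traitCoefficients = attr(clinical, "coefficients"),
        config = config)
    ExpressionBundle(x, cohort, clinical = clinical, groundTruth = truth)
}

# Clinical traits: primary trait (SLEDAI) loads on the configured latent
# factors; remaining traits carry cohort-level shifts plus noise at the
# scales reported for active disease (SLEDAI ~8 (1.7), CRP ~12 mg/L,
# C3 ~82 mg/dL, C4 ~13 mg/dL, anti-dsDNA ~100 IU/mL).
.generateTraits <- function(config, factors, cohort) {
    n <- length(cohort)
    tl <- config$traitLoadings
    lin <- rep(0, n)
    for (m in names(tl))
        if (as.integer(m) <= ncol(factors))
            lin <- lin + tl[[m]] * factors[, as.integer(m)]
    sledai <- pmax(0, round(8 * cohort + lin + rnorm(n, 0, 0.5)))
    clin <- data.frame(
        SLEDAI = sledai,
        anti_dsDNA = pmax(0, 90 * cohort + 10 + rnorm(n, 0, 20)),
        C3 = pmax(0, 110 - 28 * cohort + rnorm(n, 0, 10)),
        C4 = pmax(0, 20 - 7 * cohort + rnorm(n, 0, 2)),
        CRP = pmax(0, 3 + 9 * cohort + rnorm(n, 0, 2)),
        row.names = rownames(factors))
    attr(clin, "coefficients") <- list(SLEDAI = tl, cohortShift = c(
        SLEDAI = 8, anti_dsDNA = 90, C3 = -28, C4 = -7, CRP = 9))
    clin
}

#' Generate a gene-category taxonomy with a planted enrichment
#'
#' Emulates curated cell-type / functional classification schemes: a named
#' collection of (possibly overlapping) gene categories over the bundle's
#' gene universe. By default the `"cell"` type mimics a hematopoietic
#' cell-marker taxonomy of 32 categories whose union covers 926 genes; the
#' `"function"` type mimics a broader functional grouping of 52 categories.
#' One category ("plantedCell01" / first category) is constructed so that
#' its overlap with the planted signal genes realizes a configured odds
#' ratio against the gene universe.
#'
#' @param config a [simConfig()] object (defines the gene universe).
#' @param truth ground-truth record from [generateExpression()] (supplies
#'   the signal-gene list); may be NULL for `plantedOR = 1`.
#' @param type `"cell"` (32 categories, union 926) or `"function"`
#'   (52 categories).
#' @param nCategories,unionSize override the defaults for the chosen type.
#' @param plantedOR target odds ratio of the planted category among signal
#'   genes (1 = no enrichment planted).
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return named list of character vectors, with attributes
#'   `plantedCategory` and `plantedOR`.
#' @export
generateTaxonomy <- function(config, truth = NULL,
                             type = c("cell", "function"),
                             nCategories = NULL, unionSize = NULL,
                             plantedOR = 3, seed = NULL) {
    type <- match.arg(type)
    if (is.null(nCategories))
        nCategories <- if (type == "cell") 32L else 52L
    if (is.null(unionSize))
        unionSize <- if (type == "cell")
            min(926L, as.integer(config$nGenes %/% 2L)) else
            min(config$nGenes %/% 2L, 52L * 150L)
    if (unionSize > config$nGenes)
        stop("taxonomy union cannot exceed the gene universe")
    set.seed(if (is.null(seed)) config$seed + 1L else seed)
    geneIds <- sprintf("G%05d", seq_len(config$nGenes))
    signal <- if (!is.null(truth)) names(truth$signalGenes) else character()

    # partition a sampled union into categories, then add mild overlap
    universeDraw <- sample(geneIds, unionSize)
    sizes <- rep(unionSize %/% nCategories, nCategories)
    rem <- unionSize - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    cuts <- c(0L, cumsum(sizes))
    cats <- lapply(seq_len(nCategories), function(i)
        universeDraw[(cuts[i] + 1L):cuts[i + 1L]])
    names(cats) <- sprintf("%s%02d",
                           if (type == "cell") "cellType" else "funcGroup",
                           seq_len(nCategories))
    # overlap: each category borrows a few genes from its neighbour
    for (i in seq_len(nCategories - 1L))
        cats[[i]] <- unique(c(cats[[i]], cats[[i + 1L]][seq_len(
            min(3L, length(cats[[i + 1L]])))]))

    planted <- NA_character_
    if (plantedOR != 1 && length(signal)) {
        k <- length(cats[[1L]])
        planted <- names(cats)[1L]
        a <- .solvePlantedOverlap(plantedOR, k, length(signal),
                                  config$nGenes)
        inSig <- sample(signal, min(a, length(signal)))
        outSig <- sample(setdiff(geneIds, signal), k - length(inSig))
        cats[[1L]] <- c(inSig, outSig)
    }
    structure(cats, plantedCategory = planted, plantedOR = plantedOR,
              taxonomyType = type)
}

# Solve a(d)/(bc) = or for the overlap count a of a category of size k with
# a list of size m in a universe of size N (quadratic in a; nearest integer)
.solvePlantedOverlap <- function(or, k, m, N) {
    f <- function(a) {
        b <- m - a; cc <- k - a; d <- N - m - cc
        (a * d) / (b * cc)
    }
    grid <- seq_len(min(k, m) - 1L)
    a <- grid[which.min(abs(vapply(grid, f, numeric(1)) - or))]
    max(1L, a)
}

#' Generate a perturbagen connectivity-score table with planted targets
#'
#' Emulates the output of a connectivity-mapping query: one row per
#' perturbagen with its perturbation type (`compound`, `KD`, `OE`), a
#' connectivity score in [-100, 100] (-100 = transcriptional program
#' perfectly opposing the query signature), an optional drug-target
#' annotation and a mode-of-action direction. Planted target groups receive
#' exactly the scores supplied (or draws around a supplied mean); decoy
#' rows fall outside the canonical filter ranges and one agonist/antagonist
#' pair is made direction-inconsistent so filters can be exercised.
#'
#' @param groups data.frame with columns `target`, `type`, and either a
#'   `scores` list-column (exact scores) or `mean`/`sd`/`n` columns;
#'   optional `moa` (direction for all members). NULL or zero rows gives a
#'   decoy-only table.
#' @param nDecoys number of decoy rows outside the filter ranges.
#' @param inconsistentPair add one same-side agonist/antagonist pair
#'   (target "decoyInconsistent").
#' @param seed RNG seed.
#' @return data.frame with columns perturbagen, type, score, target,
#'   moa_direction.
#' @export
generateConnectivityTable <- function(groups = NULL, nDecoys = 20L,
                                      inconsistentPair = TRUE, seed = 1L) {
    set.seed(seed)
    rows <- list()
    if (!is.null(groups) && nrow(as.data.frame(groups))) {
        groups <- as.data.frame(groups)
        for (i in seq_len(nrow(groups))) {
            g <- groups[i, ]
            sc <- if (!is.null(groups$scores)) unlist(g$scores) else
                rnorm(g$n, g$mean, g$sd)
            if (any(sc < -100 | sc > 100))
                stop("connectivity scores must lie in [-100, 100]")
            moa <- if (!is.null(groups$moa)) g$moa else NA_character_
            rows[[length(rows) + 1L]] <- data.frame(
                perturbagen = sprintf("%s_cpd%02d", g$target, seq_along(sc)),
                type = if (!is.null(groups$type)) g$type else "compound",
                score = sc, target = g$target,
                moa_direction = moa, stringsAsFactors = FALSE)
        }
    }
    if (nDecoys > 0) {
        # decoys: scores outside (-100,-75] for compounds/KD and [50,100)
        # for OE -- i.e. in (-75, 50)
        rows[[length(rows) + 1L]] <- data.frame(
            perturbagen = sprintf("decoy%03d", seq_len(nDecoys)),
            type = sample(c("compound", "KD", "OE"), nDecoys, replace = TRUE),
            score = runif(nDecoys, -74.9, 49.9),
            target = sprintf("decoyTarget%02d",
                             sample.int(max(2L, nDecoys %/% 2L), nDecoys,
                                        replace = TRUE)),
            moa_direction = NA_character_, stringsAsFactors = FALSE)
    }
    if (inconsistentPair) {
        rows[[length(rows) + 1L]] <- data.frame(
            perturbagen = c("incons_ago", "incons_anta"),
            type = "compound", score = c(-90, -85),
            target = "decoyInconsistent",
            moa_direction = c("agonist", "antagonist"),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
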