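#' Build a pipeline configuration
#'
#' Collects per-stage parameter blocks into a validated configuration for
#' [runPipeline()]. Input can be a synthetic-data configuration (default)
#' or paths to an expression TSV and clinical CSV.
#'
#' @param outDir output directory (created if absent).
#' @param seed integer seed controlling every random stage.
#' @param simulation a [simConfig()] (used when `expressionPath` is NULL).
#' @param expressionPath,clinicalPath optional input files for real data.
#' @param taxonomyPath optional GMT of gene categories (required for real
#'   data; synthetic runs generate one).
#' @param connectivityPath optional CSV of perturbagen connectivity scores
#'   (synthetic runs generate one).
#' @param filter list(threshold =) low-intensity cutoff.
#' @param de list(fdr =) differential-expression gate.
#' @param enrich list(alpha =, plantedOR =) enrichment options.
#' @param network a [networkParams()] (set `minSize` to the scale of the
#'   data).
#' @param score list(tau =, mode =, iqrQuantile =) scoring options.
#' @param refine list(f =, alpha =) signature-refinement options.
#' @param connect list(minCount =) connectivity summary options.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(outDir, seed = 1L, simulation = simConfig(),
                           expressionPath = NULL, clinicalPath = NULL,
                           taxonomyPath = NULL, connectivityPath = NULL,
                           filter = list(threshold = 2.34),
                           de = list(fdr = 0.2),
                           enrich = list(alpha = 0.05, plantedOR = 3),
                           network = networkParams(),
                           score = list(tau = 1, mode = "diff",
                                        iqrQuantile = 0.5),
                           refine = list(f = 0.25, alpha = 0.05),
                           connect = list(minCount = 2L)) {
    if (!is.null(expressionPath) && !file.exists(expressionPath))
        stop("expression file not found: ", expressionPath)
    if (!is.null(clinicalPath) && !file.exists(clinicalPath))
        stop("clinical file not found: ", clinicalPath)
    structure(list(outDir = outDir, seed = as.integer(seed),
                   simulation = simulation,
                   expressionPath = expressionPath,
                   clinicalPath = clinicalPath,
                   taxonomyPath = taxonomyPath,
                   connectivityPath = connectivityPath,
                   filter = filter, de = de,
                   enrich = enrich, network = network, score = score,
                   refine = refine, connect = connect),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipelineConfig()]; `simulation` and `network` blocks are passed to
#'   [simConfig()] / [networkParams()].
#' @return list of class `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$simulation))
        y$simulation <- do.call(simConfig, y$simulation)
    if (!is.null(y$network))
        y$network <- do.call(networkParams, y$network)
    do.call(pipelineConfig, y)
}

#' Run the immunoprofiling pipeline end to end
#'
#' Stage order: simulate (or load) -> preprocess (low-intensity filter,
#' outlier screen) -> differential expression -> taxonomy enrichment ->
#' co-expression network (with trait correlation when clinical data are
#' present, otherwise skipped with a warning) -> per-sample gene-set
#' scoring with cohort contrasts -> signature refinement -> connectivity
#' summarization. Every intermediate is written as plain CSV/GMT/JSON
#' under `outDir`, and a manifest (parameters, output list, md5 hashes)
#' makes the run auditable. Deterministic given config + seed.
#'
#' @param config a [pipelineConfig()] result.
#' @return invisibly, a list with each stage's in-memory result and the
#'   manifest.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character()
    note <- function(path) outputs[[length(outputs) + 1L]] <<- path
    emit <- function(df, name) {
        path <- file.path(config$outDir, name)
        write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
        note(path)
        path
    }
    stage <- function(name, expr) {
        message("[pipeline] stage: ", name)
        tryCatch(expr, error = function(e) {
            manifest <- list(failedStage = name,
                             error = conditionMessage(e),
                             outputs = unlist(outputs))
            jsonlite::write_json(manifest,
                file.path(config$outDir, "manifest.json"),
                auto_unbox = TRUE, pretty = TRUE)
            stop("pipeline aborted in stage '", name, "': ",
                 conditionMessage(e), call. = FALSE)
        })
    }
    res <- list()

    bundle <- stage("input", {
        if (is.null(config$expressionPath)) {
            cfg <- config$simulation
            cfg$seed <- config$seed
            b <- generateExpression(cfg)
            gt <- groundTruth(b)
            jsonlite::write_json(
                list(signalGenes = as.list(gt$signalGenes),
                     moduleGenes = gt$moduleGenes),
                file.path(config$outDir, "ground_truth.json"),
                auto_unbox = TRUE)
            note(file.path(config$outDir, "ground_truth.json"))
            b
        } else {
            readExpression(config$expressionPath,
                           clinical = config$clinicalPath)
        }
    })

    bundle <- stage("preprocess", {
        b <- filterLowIntensity(bundle, "threshold",
                                threshold = config$filter$threshold)
        out <- detectOutlierSamples(b)
        emit(data.frame(sample = names(out$pcDistance),
                        pcDistance = out$pcDistance,
                        pcFlag = out$pcFlag, dendroFlag = out$dendroFlag,
                        flagged = names(out$pcDistance) %in% out$flagged),
             "outlier_screen.csv")
        if (length(out$flagged))
            b <- b[, setdiff(colnames(b), out$flagged)]
        b
    })

    res$de <- stage("de", {
        de <- fitModerated(bundle, fdr = config$de$fdr)
        emit(deTable(de), "differential_expression.csv")
        de
    })

    res$enrichment <- stage("enrich", {
        truth <- groundTruth(bundle)
        tax <- if (!is.null(config$taxonomyPath)) {
            readGMT(config$taxonomyPath)
        } else if (!is.null(truth)) {
            generateTaxonomy(config$simulation, truth,
                             plantedOR = config$enrich$plantedOR,
                             seed = config$seed + 1L)
        } else stop("real-data runs need a taxonomy GMT")
        writeGMT(tax, file.path(config$outDir, "taxonomy.gmt"))
            note(file.path(config$outDir, "taxonomy.gmt"))
        tab <- deTable(res$de)
        degs <- tab$gene[tab$significant & tab$lfc > 0]
        universe <- rownames(bundle)
        if (length(degs) < 2L) degs <- tab$gene[order(tab$p)][1:50]
        rec <- enrichAll(intersect(degs, universe), tax, universe,
                         alpha = config$enrich$alpha)
        emit(rec, "enrichment.csv")
        rec
    })

    res$network <- stage("net", {
        np <- config$network
        tom <- buildTOM(bundle, np)
        ms <- detectModules(tom, np)
        if (any(moduleLabels(ms) != "grey")) {
            ms <- computeEigengenes(bundle, ms)
            ms <- mergeModules(bundle, ms)
            if (ncol(clinicalData(bundle)) > 0) {
                ms <- correlateTraits(ms, bundle)
                emit(moduleTraitCor(ms), "module_trait_correlation.csv")
            } else {
                warning("no clinical table; trait-correlation stage skipped")
            }
            emit(data.frame(gene = names(moduleLabels(ms)),
                            module = moduleLabels(ms)),
                 "module_assignment.csv")
            emit(data.frame(sample = rownames(moduleEigengenes(ms)),
                            moduleEigengenes(ms), check.names = FALSE),
                 "module_eigengenes.csv")
        }
        ms
    })

    res$scores <- stage("score", {
        b <- filterLowIntensity(bundle, "iqr",
                                iqrQuantile = config$score$iqrQuantile)
        truth <- groundTruth(bundle)
        sets <- if (!is.null(truth) && length(truth$moduleGenes)) {
            lapply(truth$moduleGenes, intersect, y = rownames(b))
        } else {
            list(topVar = rownames(b)[order(-apply(exprValues(b), 1, var))
                                      ][seq_len(min(50, nrow(b)))])
        }
        sets <- sets[lengths(sets) >= 3L]
        st <- expressionStatistic(b)
        sc <- enrichmentScores(st, sets, tau = config$score$tau,
                               mode = config$score$mode)
        cmp <- compareGroups(sc, cohortLabels(b))
        emit(data.frame(set = rownames(sc), sc, check.names = FALSE),
             "gene_set_scores.csv")
        emit(cmp, "score_contrasts.csv")
        list(scores = sc, contrasts = cmp)
    })

    res$refined <- stage("refine", {
        truth <- groundTruth(bundle)
        sigGenes <- if (!is.null(truth) && length(truth$moduleGenes))
            intersect(truth$moduleGenes[[1]], rownames(bundle)) else
            rownames(bundle)[seq_len(min(20L, nrow(bundle)))]
        ref <- refineSignature(bundle, sigGenes, f = config$refine$f,
                               alpha = config$refine$alpha)
        writeGMT(list(refined = ref$refined),
                 file.path(config$outDir, "refined_signature.gmt"))
            note(file.path(config$outDir, "refined_signature.gmt"))
        jsonlite::write_json(ref$audit,
            file.path(config$outDir, "refinement_audit.json"))
            note(file.path(config$outDir, "refinement_audit.json"))
        ref
    })

    res$targets <- stage("connect", {
        ct <- if (!is.null(config$connectivityPath)) {
            read.delim(config$connectivityPath, sep = ",",
                       stringsAsFactors = FALSE)
        } else {
            groups <- data.frame(
                target = c("targetA", "targetB"),
                type = "compound", mean = c(-90, -85), sd = 3, n = 3L)
            generateConnectivityTable(groups, seed = config$seed + 2L)
        }
        filt <- filterConnectivity(ct)
        summ <- summarizeTargets(filt, minCount = config$connect$minCount)
        emit(formatTargetTable(summ), "target_summary.csv")
        burs <- rankRegulators(filt)
        jsonlite::write_json(burs,
            file.path(config$outDir, "upstream_regulators.json"))
            note(file.path(config$outDir, "upstream_regulators.json"))
        summ
    })

    manifest <- list(
        package = as.character(utils::packageVersion("immunoprofiler")),
        seed = config$seed,
        parameters = config[setdiff(names(config), "outDir")],
        outputs = unlist(outputs),
        md5 = as.list(tools::md5sum(unlist(outputs))))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    res$manifest <- manifest
    invisible(res)
}
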