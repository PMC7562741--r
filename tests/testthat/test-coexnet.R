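test_that("TOM matches the brute-force formula on random adjacencies", {
    set.seed(51)
    for (rep in 1:3) {
        p <- 8
        a <- matrix(runif(p * p), p)
        a <- (a + t(a)) / 2
        diag(a) <- 1
        dimnames(a) <- list(sprintf("g%d", 1:p), sprintf("g%d", 1:p))
        tom <- immunoprofiler:::.tomFromAdjacency(a)
        expect_equal(tom, oracleTOM(a), tolerance = 1e-12)
    }
})

test_that("TOM is symmetric with unit diagonal and values in [0, 1]", {
    b <- randomBundle(nGenes = 40, n1 = 5, n2 = 5, seed = 52)
    tom <- buildTOM(b, networkParams(power = 6, minSize = 5))
    expect_equal(tom, t(tom))
    expect_equal(unname(diag(tom)), rep(1, 40))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("genes identical up to positive affine transform have TOM 1", {
    set.seed(50)
    x <- rnorm(10)
    m <- rbind(g1 = x, g2 = 2 * x + 5)
    b <- makeBundle(m, cohort = rep(c(1, 0), 5))
    tom <- buildTOM(b, networkParams(power = 6, minSize = 3))
    expect_equal(unname(abs(cor(x, 2 * x + 5))^6), 1)
    expect_equal(unname(tom["g1", "g2"]), 1, tolerance = 1e-10)
})

test_that("zero-variance genes are rejected by name", {
    m <- rbind(flat = rep(3, 6), ok = rnorm(6))
    b <- makeBundle(m)
    expect_error(buildTOM(b, networkParams(minSize = 3)), "flat")
})

test_that("independent genes produce near-zero topological overlap", {
    set.seed(53)
    hit <- vapply(1:20, function(i) {
        m <- matrix(rnorm(30 * 20), 30, 20)
        rownames(m) <- sprintf("g%d", 1:30)
        colnames(m) <- sprintf("s%d", 1:20)
        tom <- buildTOM(makeBundle(m), networkParams(power = 30,
                                                     minSize = 3))
        max(tom[upper.tri(tom)]) < 0.05
    }, logical(1))
    expect_gte(mean(hit), 0.99)
})

test_that("noise-free planted blocks are recovered exactly", {
    set.seed(54)
    n <- 12
    f1 <- rnorm(n); f2 <- rnorm(n)
    lam <- runif(240, 0.7, 1.3)
    m <- rbind(outer(lam[1:120], f1), outer(lam[121:240], f2))
    rownames(m) <- sprintf("g%03d", 1:240)
    colnames(m) <- sprintf("s%02d", 1:n)
    b <- makeBundle(m)
    ms <- detectModules(buildTOM(b, networkParams()), networkParams())
    lab <- moduleLabels(ms)
    expect_identical(length(unique(lab)), 2L)
    expect_identical(length(unique(lab[1:120])), 1L)
    expect_identical(length(unique(lab[121:240])), 1L)
    expect_false(unique(lab[1:120]) == unique(lab[121:240]))
})

test_that("min size beyond the gene count leaves all genes grey", {
    b <- randomBundle(nGenes = 20, n1 = 5, n2 = 5, seed = 55)
    np <- networkParams(minSize = 50)
    expect_warning(ms <- detectModules(buildTOM(b, np), np), "grey")
    expect_true(all(moduleLabels(ms) == "grey"))
})

test_that("module recovery is invariant to gene order", {
    cfg <- simConfig(nGenes = 300, nPerCohort = c(10, 10), nSignal = 0,
                     lfcRange = c(0, 0), nModules = 2, moduleSize = 120,
                     seed = 56)
    b <- generateExpression(cfg)
    np <- networkParams()
    lab1 <- moduleLabels(detectModules(buildTOM(b, np), np))
    set.seed(1)
    perm <- sample(nrow(b))
    bp <- makeBundle(exprValues(b)[perm, ], cohort = cohortLabels(b))
    lab2 <- moduleLabels(detectModules(buildTOM(bp, np), np))
    expect_identical(lab1[rownames(b)], lab2[rownames(b)])
})

test_that("eigengenes match a direct SVD and fix their sign", {
    cfg <- simConfig(nGenes = 200, nPerCohort = c(8, 8), nSignal = 0,
                     lfcRange = c(0, 0), nModules = 2, moduleSize = 60,
                     seed = 57)
    b <- generateExpression(cfg)
    gt <- groundTruth(b)
    lab <- setNames(rep("grey", nrow(b)), rownames(b))
    lab[gt$moduleGenes[["1"]]] <- "turquoise"
    lab[gt$moduleGenes[["2"]]] <- "blue"
    ms <- new("ModuleSet", labels = lab, ME = matrix(numeric(0), 0, 0),
              kME = matrix(numeric(0), 0, 0), traitCor = data.frame(),
              params = unclass(networkParams()), qc = list())
    ms <- computeEigengenes(b, ms)
    for (md in c("turquoise", "blue")) {
        z <- t(scale(t(exprValues(b)[names(lab)[lab == md], ])))
        sv <- svd(z)
        me <- moduleEigengenes(ms)[, md]
        expect_equal(abs(sum(me * sv$v[, 1])), 1, tolerance = 1e-10)
        expect_gt(cor(me, colMeans(z)), 0)   # sign convention
        expect_equal(ms@qc$varExplained[[md]],
                     sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
    }
    expect_true(all(abs(moduleMembership(ms)) <= 1 + 1e-8))
})

test_that("a module of identical genes has ME equal to the common profile", {
    x <- rnorm(8)
    m <- rbind(g1 = x, g2 = x, g3 = x, g4 = rnorm(8))
    b <- makeBundle(m, cohort = rep(c(1, 0), each = 4))
    lab <- setNames(c("turquoise", "turquoise", "turquoise", "grey"),
                    rownames(m))
    ms <- new("ModuleSet", labels = lab, ME = matrix(numeric(0), 0, 0),
              kME = matrix(numeric(0), 0, 0), traitCor = data.frame(),
              params = list(), qc = list())
    ms <- computeEigengenes(b, ms)
    me <- moduleEigengenes(ms)[, "turquoise"]
    expect_equal(abs(cor(me, x)), 1, tolerance = 1e-10)
    expect_equal(unname(moduleMembership(ms)[c("g1", "g2", "g3"),
                                             "turquoise"]),
                 rep(1, 3), tolerance = 1e-10)
})

test_that("modules with correlated eigengenes merge below the merge height", {
    set.seed(58)
    n <- 16
    f1 <- rnorm(n)
    f2 <- 0.97 * f1 + sqrt(1 - 0.97^2) * rnorm(n)   # cor ~ 0.97
    f3 <- rnorm(n)                                   # independent
    mk <- function(f, k) outer(runif(k, 0.8, 1.2), f) +
        matrix(rnorm(k * n, 0, 0.1), k)
    m <- rbind(mk(f1, 30), mk(f2, 30), mk(f3, 30))
    rownames(m) <- sprintf("g%03d", 1:90)
    colnames(m) <- sprintf("s%02d", 1:n)
    b <- makeBundle(m)
    lab <- setNames(rep(c("turquoise", "blue", "brown"), each = 30),
                    rownames(m))
    ms <- new("ModuleSet", labels = lab, ME = matrix(numeric(0), 0, 0),
              kME = matrix(numeric(0), 0, 0), traitCor = data.frame(),
              params = unclass(networkParams()), qc = list())
    ms <- computeEigengenes(b, ms)
    cors <- cor(moduleEigengenes(ms))
    expect_gt(cors["turquoise", "blue"], 0.8)       # will merge at 0.2
    expect_lt(abs(cors["turquoise", "brown"]), 0.5) # will not merge
    merged <- mergeModules(b, ms, mergeHeight = 0.2)
    lab2 <- moduleLabels(merged)
    expect_identical(length(unique(lab2[1:60])), 1L)
    expect_identical(length(unique(lab2[61:90])), 1L)
    expect_identical(length(unique(lab2)), 2L)
})

test_that("eigengene merging equals brute-force agglomeration on a chain", {
    # three MEs with pairwise dissimilarities 0.1 (a,b), 0.15 (b,c),
    # 0.5 (a,c): complete linkage at height 0.2 merges a+b only
    d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.15, 0.5, 0.15, 0), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    grp <- cutree(hclust(as.dist(d), method = "complete"), h = 0.2)
    expect_identical(grp[["a"]], grp[["b"]])
    expect_false(grp[["a"]] == grp[["c"]])
})

test_that("module-trait correlation matches textbook Pearson", {
    cfg <- simConfig(nGenes = 150, nPerCohort = c(10, 10), nSignal = 0,
                     lfcRange = c(0, 0), nModules = 1, moduleSize = 60,
                     traitLoadings = c("1" = 3), seed = 59)
    b <- generateExpression(cfg)
    gt <- groundTruth(b)
    lab <- setNames(rep("grey", nrow(b)), rownames(b))
    lab[gt$moduleGenes[["1"]]] <- "turquoise"
    ms <- new("ModuleSet", labels = lab, ME = matrix(numeric(0), 0, 0),
              kME = matrix(numeric(0), 0, 0), traitCor = data.frame(),
              params = list(), qc = list())
    ms <- correlateTraits(computeEigengenes(b, ms), b)
    tc <- moduleTraitCor(ms)
    me <- moduleEigengenes(ms)[, "turquoise"]
    sled <- clinicalData(b)$SLEDAI
    rOracle <- sum((me - mean(me)) * (sled - mean(sled))) /
        sqrt(sum((me - mean(me))^2) * sum((sled - mean(sled))^2))
    expect_equal(tc$r[tc$trait == "SLEDAI"], rOracle, tolerance = 1e-12)
    # a trait equal to the ME itself: r = 1, p ~ 0
    b2 <- ExpressionBundle(exprValues(b), cohortLabels(b),
                           clinical = data.frame(me = me - min(me),
                                                 row.names = colnames(b)))
    tc2 <- moduleTraitCor(correlateTraits(ms, b2))
    expect_equal(tc2$r[tc2$trait == "me"], 1, tolerance = 1e-12)
    expect_lt(tc2$p[tc2$trait == "me"], 1e-12)
})

test_that("constant traits are reported as NA with a reason", {
    b <- randomBundle(nGenes = 40, seed = 60)
    lab <- setNames(rep("turquoise", 40), rownames(b))
    ms <- new("ModuleSet", labels = lab, ME = matrix(numeric(0), 0, 0),
              kME = matrix(numeric(0), 0, 0), traitCor = data.frame(),
              params = list(), qc = list())
    ms <- computeEigengenes(b, ms)
    b2 <- ExpressionBundle(exprValues(b), cohortLabels(b),
                           clinical = data.frame(flat = rep(5, 8),
                                                 row.names = colnames(b)))
    tc <- moduleTraitCor(correlateTraits(ms, b2))
    expect_true(is.na(tc$r[tc$trait == "flat"]))
    expect_identical(tc$note[tc$trait == "flat"], "constant trait")
})

test_that("uncorrelated traits rarely reach |r| > 0.5 at n = 8", {
    b <- randomBundle(nGenes = 30, seed = 61)
    lab <- setNames(rep("turquoise", 30), rownames(b))
    ms <- new("ModuleSet", labels = lab, ME = matrix(numeric(0), 0, 0),
              kME = matrix(numeric(0), 0, 0), traitCor = data.frame(),
              params = list(), qc = list())
    ms <- computeEigengenes(b, ms)
    me <- moduleEigengenes(ms)[, 1]
    set.seed(62)
    rs <- replicate(1000, abs(cor(me, rnorm(8))))
    # P(|r| <= 0.5) for independent normals at n = 8 is
    # 1 - 2 pt(-0.5 sqrt(6/0.75), 6) = 0.793; allow 3 sigma of MC noise
    expect_lt(abs(mean(rs <= 0.5) - 0.793), 0.04)
})

test_that("module QC: concordance, sign consistency, strength boundary", {
    cfg <- simConfig(nGenes = 300, nPerCohort = c(10, 10), nSignal = 0,
                     lfcRange = c(0, 0), nModules = 1, moduleSize = 130,
                     traitLoadings = c("1" = 5), seed = 63)
    b <- generateExpression(cfg)
    np <- networkParams()
    ms <- detectModules(buildTOM(b, np), np)
    ms <- correlateTraits(computeEigengenes(b, ms), b)
    md <- setdiff(unique(moduleLabels(ms)), "grey")[1]
    qc <- qcModule(ms, b, md, trait = "SLEDAI")
    expect_gt(qc$concordance, 0.5)
    sled <- qc$traitClassification
    expect_true(sled$strong[sled$trait == "SLEDAI"])

    # permuted trait: the strong call should almost never survive
    set.seed(64)
    strongPerm <- vapply(1:200, function(i) {
        clin <- clinicalData(b)
        clin$SLEDAI <- sample(clin$SLEDAI)
        b2 <- ExpressionBundle(exprValues(b), cohortLabels(b),
                               clinical = clin)
        ms2 <- correlateTraits(ms, b2)
        qc2 <- qcModule(ms2, b2, md, trait = "SLEDAI")
        tcl <- qc2$traitClassification
        tcl$strong[tcl$trait == "SLEDAI"]
    }, logical(1))
    expect_gte(mean(!strongPerm), 0.95)
})

test_that("the strong-correlation boundary is inclusive at |r| = 0.5", {
    ms <- new("ModuleSet",
              labels = setNames("turquoise", "g1"),
              ME = matrix(rnorm(8), 8, 1,
                          dimnames = list(sprintf("s%d", 1:8), "turquoise")),
              kME = matrix(0.9, 1, 1,
                           dimnames = list("g1", "turquoise")),
              traitCor = data.frame(module = "turquoise", trait = "SLEDAI",
                                    r = 0.5, p = 0.049, n = 8, note = ""),
              params = list(), qc = list())
    b <- makeBundle(matrix(rnorm(8), 1, 8,
                           dimnames = list("g1", sprintf("s%d", 1:8))),
                    cohort = rep(c(1, 0), each = 4))
    qc <- qcModule(ms, b, "turquoise")
    expect_true(qc$traitClassification$strong)
    ms@traitCor$p <- 0.051
    expect_false(qcModule(ms, b, "turquoise")$traitClassification$strong)
})
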