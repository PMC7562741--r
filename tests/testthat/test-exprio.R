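test_that("expression matrices round-trip through TSV and CSV", {
    b <- randomBundle(nGenes = 3, n1 = 1, n2 = 1, seed = 1)
    for (fmt in c("tsv", "csv")) {
        path <- tempfile(fileext = paste0(".", fmt))
        writeExpression(b, path, fmt)
        b2 <- readExpression(path, fmt, cohort = cohortLabels(b))
        expect_equal(exprValues(b2), exprValues(b))
    }
})

test_that("malformed expression files are rejected with informative errors", {
    path <- tempfile()
    writeLines(c("gene\ts1\ts1", "g1\t1\t2"), path)
    expect_error(readExpression(path, cohort = c(1, 0)), "duplicate sample")
    writeLines(c("gene\ts1\ts2", "g1\t1\tx"), path)
    expect_error(readExpression(path, cohort = c(1, 0)), "non-numeric")
    writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), path)
    expect_error(readExpression(path, cohort = c(1, 0)), "duplicate gene")
})

test_that("GMT files parse and round-trip", {
    path <- tempfile(fileext = ".gmt")
    writeLines("A\tdesc\tg1\tg2", path)
    sets <- readGMT(path)
    expect_identical(sets, list(A = c("g1", "g2")))
    writeGMT(list(B = c("x", "y", "z")), path)
    expect_identical(readGMT(path), list(B = c("x", "y", "z")))
    writeLines("A\tonly-desc", path)
    expect_error(readGMT(path), "malformed")
})

test_that("threshold filtering drops genes that never clear the cutoff", {
    m <- rbind(low = rep(2.0, 4), high = c(1, 1, 1, 5),
               mid = rep(2.34, 4))
    b <- makeBundle(m)
    f <- filterLowIntensity(b, "threshold", threshold = 2.34)
    # kept iff max >= 2.34: 'low' removed, 'high' and boundary 'mid' kept
    expect_setequal(rownames(f), c("high", "mid"))
    expect_identical(rownames(filterLowIntensity(b, "threshold",
                                                 threshold = -Inf)),
                     rownames(b))
    expect_error(filterLowIntensity(b, "threshold", threshold = 100),
                 "every gene")
})

test_that("IQR filtering matches brute-force per-gene recomputation", {
    set.seed(9)
    m <- matrix(rnorm(5 * 8, 7, c(0.1, 0.5, 1, 2, 4)), 5, 8)
    b <- makeBundle(m)
    f <- filterLowIntensity(b, "iqr", iqrQuantile = 0.5)
    iqr <- apply(m, 1, function(x) unname(diff(quantile(x, c(.25, .75)))))
    keep <- iqr >= quantile(iqr, 0.5)
    expect_setequal(rownames(f), rownames(exprValues(b))[keep])
})

test_that("filtering is idempotent", {
    b <- randomBundle(nGenes = 50, seed = 4)
    f1 <- filterLowIntensity(b, "threshold", threshold = 7)
    f2 <- filterLowIntensity(f1, "threshold", threshold = 7)
    expect_identical(exprValues(f1), exprValues(f2))
})

test_that("outlier screen flags a strongly shifted sample and only then", {
    set.seed(21)
    m <- matrix(rnorm(200 * 8, 7, 1), 200, 8)
    b0 <- makeBundle(m, cohort = rep(c(1, 0), each = 4))
    m2 <- m
    m2[, 8] <- m2[, 8] + 10     # +10 sd on every gene
    b1 <- makeBundle(m2, cohort = rep(c(1, 0), each = 4))
    out <- detectOutlierSamples(b1)
    expect_identical(out$flagged, "s08")
    # oracle: direct euclidean distance in PC space dwarfs the others
    expect_gt(out$pcDistance["s08"], 3 * mad(out$pcDistance))
    expect_length(detectOutlierSamples(b0)$flagged, 0L)
    expect_length(detectOutlierSamples(b1, k = Inf)$flagged, 0L)
})

test_that("identical samples produce no outlier flags", {
    m <- matrix(rep(1:10, 6), 10, 6)
    b <- makeBundle(m)
    expect_length(detectOutlierSamples(b)$flagged, 0L)
    expect_error(detectOutlierSamples(makeBundle(m[, 1:3])),
                 "insufficient samples")
})

test_that("outlier screen is invariant to gene order and global shifts", {
    set.seed(22)
    m <- matrix(rnorm(100 * 8, 7, 1), 100, 8)
    m[, 1] <- m[, 1] + 6
    b <- makeBundle(m, cohort = rep(c(1, 0), each = 4))
    o1 <- detectOutlierSamples(b)
    o2 <- detectOutlierSamples(makeBundle(m[sample(100), , drop = FALSE],
                                          cohort = rep(c(1, 0), each = 4)))
    o3 <- detectOutlierSamples(makeBundle(m + 5,
                                          cohort = rep(c(1, 0), each = 4)))
    expect_identical(o1$flagged, o2$flagged)
    expect_identical(o1$flagged, o3$flagged)
    expect_equal(o1$pcDistance, o3$pcDistance)
})

test_that("probe collapse keeps the rule-selected probe per gene", {
    m <- matrix(c(1, 2, 3, 4, 5, 6, 2, 2, 2, 9, 9, 9), 4, 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3", "p4"), c("a", "b", "c")))
    pm <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                     gene = c("G1", "G1", "G2", "G2"))
    b <- makeBundle(m, cohort = c(1, 1, 0))
    col <- collapseProbes(b, pm, "max_mean")
    expect_setequal(rownames(col), c("G1", "G2"))
    expect_equal(unname(exprValues(col)["G1", ]), c(4, 5, 6))
    expect_equal(unname(exprValues(col)["G2", ]), c(9, 9, 9))
    # identity when one probe per gene
    pm1 <- data.frame(probe = rownames(m), gene = paste0("u", 1:4))
    expect_identical(nrow(collapseProbes(b, pm1, "max_mean")), 4L)
    expect_error(collapseProbes(b, pm, "max_kME"), "ModuleSet")
})

test_that("max_mean collapse equals an exhaustive scan on a 6-probe fixture", {
    set.seed(12)
    m <- matrix(rnorm(6 * 5, 7), 6, 5,
                dimnames = list(sprintf("p%d", 1:6), sprintf("s%d", 1:5)))
    pm <- data.frame(probe = sprintf("p%d", 1:6),
                     gene = c("A", "A", "A", "B", "B", "C"))
    b <- makeBundle(m, cohort = c(1, 1, 1, 0, 0))
    col <- collapseProbes(b, pm, "max_mean")
    for (g in c("A", "B", "C")) {
        probes <- pm$probe[pm$gene == g]
        best <- probes[which.max(rowMeans(m[probes, , drop = FALSE]))]
        expect_equal(unname(exprValues(col)[g, ]), unname(m[best, ]))
    }
    expect_identical(anyDuplicated(rownames(col)), 0L)
})

test_that("DE collapse keeps the most significant probe, ties lexicographic", {
    tab <- data.frame(gene = c("p1", "p2", "p3", "p4"),
                      lfc = c(1, 2, 1, 1), t = 1, p = c(0.01, 1e-4, 0.5, 0.5),
                      q = c(0.02, 2e-4, 0.6, 0.6),
                      significant = c(TRUE, TRUE, FALSE, FALSE),
                      source = "A", stringsAsFactors = FALSE)
    de <- new("DEResult", table = tab, prior = list(d0 = 1, s02 = 1),
              fdr = 0.2)
    pm <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                     gene = c("G1", "G1", "G2", "G2"))
    col <- deTable(collapseProbes(de, pm, "min_p"))
    expect_equal(col$p[col$gene == "G1"], 1e-4)
    expect_equal(col$lfc[col$gene == "G2"], 1)  # tie -> p3 before p4
})
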