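test_that("MAF variance follows the pooled-minor-allele convention", {
    ft <- freqTable(rbind(A = c(0.1, 0.0, 0.9),
                          B = c(0.1, 0.5, 0.8),
                          C = c(0.1, 0.25, 0.7)), 40)
    mv <- mafVariance(ft)
    expect_equal(unname(mv$mafVariance[1]), 0)
    expect_equal(unname(mv$mafVariance[2]), var(c(0, 0.5, 0.25)))
    # pooled frequency 0.8 > 0.5: fold to the reference allele
    expect_equal(unname(mv$mafVariance[3]), var(c(0.1, 0.2, 0.3)))
    expect_equal(unname(mv$popMAF[3, ]), c(0.1, 0.2, 0.3))
})

test_that("two-population variance matches the forced arithmetic", {
    ft <- freqTable(rbind(A = 0.0, B = 0.5), 40)
    expect_equal(unname(mafVariance(ft)$mafVariance), 0.125)
    expect_equal(unname(mafVariance(ft, popVariance = TRUE)$mafVariance),
                 0.0625)
})

test_that("sites without two informative populations are skipped", {
    ft <- freqTable(rbind(A = c(0.2, 0.3), B = c(NA, 0.4)),
                    rbind(c(40, 40), c(0, 40)))
    expect_message(mv <- mafVariance(ft), "1 site")
    expect_true(is.na(mv$mafVariance[1]))
    expect_false(is.na(mv$mafVariance[2]))
})

# small panel-results bundle for comparison tests
resultBundle <- function(fr, eig1 = 1) {
    list(fst = fstMatrix(fr, blocks = NULL),
         f3 = f3Scan(fr, blocks = rep(1:5,
             length.out = length(fr@pos))),
         eigenvalues = eig1, cv = NULL)
}

test_that("a panel compared with itself is the identity comparison", {
    cfg <- twoSuperConfig(nPerPop = 15L, mSnps = 500L, seed = 61L)
    fr <- alleleFrequencies(simulatePanel(cfg))
    b <- resultBundle(fr)
    cmp <- comparePanels(list(ref = b, same = b), reference = "ref")
    expect_true(all(cmp@fstDifference$same == 0))
    expect_equal(unname(cmp@f3Correlation["same"]), 1.0)
    expect_equal(unname(cmp@eigenvalueRatio["same"]), 1.0)
})

test_that("swapping panel and reference negates the difference matrix", {
    cfg <- twoSuperConfig(nPerPop = 15L, mSnps = 600L, seed = 62L)
    g <- simulatePanel(cfg)
    fr <- alleleFrequencies(g)
    b1 <- resultBundle(subsetFreqs(fr, 1:300))
    b2 <- resultBundle(subsetFreqs(fr, 301:600))
    c12 <- comparePanels(list(a = b1, b = b2), reference = "a")
    c21 <- comparePanels(list(a = b1, b = b2), reference = "b")
    expect_equal(c12@fstDifference$b, -c21@fstDifference$a)
})

test_that("independent random subsets of one site pool give near-identical f3", {
    cfg <- simConfig(tree = list(
        S1 = list(F = 0.08, pops = c(A = 0.01, B = 0.01)),
        S2 = list(F = 0.08, pops = c(C = 0.01, D = 0.01)),
        S3 = list(F = 0.08, pops = c(E = 0.01, G = 0.01))),
        nPerPop = 25L, mSnps = 20000L, seed = 63L)
    fr <- alleleFrequencies(simulatePanel(cfg))
    set.seed(1)
    s1 <- sort(sample(20000L, 10000L)); s2 <- sort(sample(20000L, 10000L))
    b1 <- resultBundle(subsetFreqs(fr, s1))
    b2 <- resultBundle(subsetFreqs(fr, s2))
    cmp <- comparePanels(list(a = b1, b = b2), reference = "a")
    expect_gt(cmp@f3Correlation["b"], 0.99)
})

test_that("population-set mismatches are reported", {
    f1 <- freqTable(rbind(A = c(0.2, 0.3, 0.4), B = c(0.3, 0.2, 0.5),
                          C = c(0.1, 0.6, 0.3)), 40)
    f2 <- freqTable(rbind(A = c(0.2, 0.3, 0.4), B = c(0.3, 0.2, 0.5),
                          D = c(0.1, 0.6, 0.3)), 40)
    blocks <- c(1, 2, 3)
    b1 <- list(fst = fstMatrix(f1, blocks = NULL),
               f3 = f3Scan(f1, blocks = blocks), eigenvalues = 1, cv = NULL)
    b2 <- list(fst = fstMatrix(f2, blocks = NULL),
               f3 = f3Scan(f2, blocks = blocks), eigenvalues = 1, cv = NULL)
    expect_error(comparePanels(list(x = b1, y = b2), reference = "x"), "D")
})

test_that("reports are deterministic and complete", {
    cfg <- twoSuperConfig(nPerPop = 10L, mSnps = 400L, seed = 64L)
    fr <- alleleFrequencies(simulatePanel(cfg))
    b1 <- resultBundle(subsetFreqs(fr, 1:200))
    b2 <- resultBundle(subsetFreqs(fr, 201:400))
    cmp <- comparePanels(list(ref = b1, alt = b2), reference = "ref")
    mv <- list(ref = mafVariance(subsetFreqs(fr, 1:200)),
               alt = mafVariance(subsetFreqs(fr, 201:400)))
    d1 <- file.path(tempfile(), "rep1"); d2 <- file.path(tempfile(), "rep2")
    f1 <- reportComparison(cmp, d1, mafVar = mv,
                           metadata = list(seed = 64))
    f2 <- reportComparison(cmp, d2, mafVar = mv,
                           metadata = list(seed = 64))
    expected <- c("fst_ref.tsv", "fst_alt.tsv", "f3_ref.tsv", "f3_alt.tsv",
                  "fst_diff_alt.tsv", "panel_summary.tsv",
                  "run_metadata.json", "f3_scatter.png",
                  "maf_variance_density.png", "maf_variance_summary.tsv")
    expect_setequal(basename(f1), expected)
    expect_true(all(file.exists(f1)))
    for (nm in grep("tsv$", expected, value = TRUE))
        expect_identical(readLines(file.path(d1, nm)),
                         readLines(file.path(d2, nm)))
    empty <- new("PanelComparison", panels = character(0),
                 reference = "x", fstDifference = list(),
                 f3Correlation = numeric(0), eigenvalueRatio = numeric(0),
                 cvCurves = list(), fstMatrices = list(), f3Tables = list())
    expect_error(reportComparison(empty, tempfile()), "empty")
})
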