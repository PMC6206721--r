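test_that("zero-drift limit leaves population frequencies at the ancestral value", {
    cfg <- simConfig(tree = list(S = list(F = 1e-9, pops = c(A = 1e-9))),
                     nPerPop = 2L, mSnps = 2000L, seed = 3L)
    fp <- simulateFrequencies(cfg)
    expect_lt(max(abs(fp@popFreq["A", ] - fp@ancestral)), 1e-3)
})

test_that("simulation is deterministic given the seed", {
    cfg <- twoSuperConfig(nPerPop = 5L, mSnps = 300L, seed = 11L)
    expect_identical(simulateFrequencies(cfg), simulateFrequencies(cfg))
    expect_identical(dosages(simulatePanel(cfg)), dosages(simulatePanel(cfg)))
})

test_that("Balding-Nichols draws are centred on the parent frequency", {
    # Beta(p(1-F)/F, (1-p)(1-F)/F) has mean p; at 50,000 sites the average
    # drift must vanish within Monte-Carlo error
    cfg <- simConfig(tree = list(S = list(F = 0.05, pops = c(A = 1e-9))),
                     nPerPop = 2L, mSnps = 50000L, seed = 5L)
    fp <- simulateFrequencies(cfg)
    dev <- fp@popFreq["A", ] - fp@ancestral
    se <- sd(dev) / sqrt(length(dev))
    expect_lt(abs(mean(dev)), 3 * se)
})

test_that("frequency bounds and genotype alphabet are preserved", {
    cfg <- twoSuperConfig(nPerPop = 10L, mSnps = 500L, seed = 2L,
                          admixture = list(list(target = "X",
                              sources = c("A", "C"), props = c(0.5, 0.5))))
    fp <- simulateFrequencies(cfg)
    expect_true(all(fp@popFreq >= 0 & fp@popFreq <= 1))
    g <- simulateGenotypes(fp, cfg)
    expect_true(all(dosages(g) %in% 0:2))
    expect_identical(sort(unique(populations(g))),
                     sort(c("A", "B", "C", "D", "X")))
})

test_that("degenerate frequencies force constant genotypes", {
    freq <- rbind(P = c(0, 1, 0.5))
    cfg <- simConfig(tree = list(S = list(F = 0.01, pops = c(P = 0.01))),
                     nPerPop = 20L, mSnps = 3L, seed = 1L)
    g <- simulateGenotypes(new("FrequencyPanel", ancestral = c(0.3, 0.3, 0.3),
                               popFreq = freq), cfg)
    d <- dosages(g)
    expect_true(all(d[1, ] == 0L))
    expect_true(all(d[2, ] == 2L))
})

test_that("a 50/50 admixed group matches its (identical) sources in mean genotype", {
    set.seed(9)
    p <- runif(400, 0.05, 0.5)
    freq <- rbind(A = p, B = p)      # zero drift between the sources
    cfg <- simConfig(tree = list(S = list(F = 0.01,
                                          pops = c(A = 0.01, B = 0.01))),
                     nPerPop = 150L, mSnps = 400L, seed = 21L,
                     admixture = list(list(target = "C",
                         sources = c("A", "B"), props = c(0.5, 0.5))))
    g <- simulateGenotypes(new("FrequencyPanel", ancestral = p,
                               popFreq = freq), cfg)
    d <- dosages(g); pops <- populations(g)
    mA <- mean(d[, pops == "A"]); mC <- mean(d[, pops == "C"])
    # binomial-mixture oracle: both means estimate 2*mean(p)
    n <- 150L * 400L
    se <- sqrt(2 * mean(2 * p * (1 - p)) / n)
    expect_lt(abs(mC - mA), 3 * sqrt(2) * se)
})

test_that("admixture sources must exist in the tree", {
    expect_error(simConfig(tree = list(S = list(F = 0.01, pops = c(A = 0.01))),
                           admixture = list(list(target = "X",
                               sources = c("A", "NOPE"),
                               props = c(0.5, 0.5)))),
                 "source not in tree")
})

test_that("invalid drift parameters are rejected", {
    expect_error(simConfig(tree = list(S = list(F = 0, pops = c(A = 0.01)))),
                 "drift")
    expect_error(simConfig(tree = list(S = list(F = 1.2, pops = c(A = 0.01)))),
                 "drift")
})

test_that("LD block injection creates perfect within-block correlation at noise 0", {
    cfg <- twoSuperConfig(nPerPop = 15L, mSnps = 100L, seed = 4L)
    g <- simulatePanel(cfg)
    gb <- injectLDBlocks(g, blockLen = 5L, noise = 0, seed = 8L)
    d <- dosages(gb)
    for (s in seq(1, 96, by = 5))
        for (j in (s + 1):(s + 4))
            expect_identical(d[j, ], d[s, ])
    expect_identical(dosages(injectLDBlocks(g, 1L, 0.3, seed = 8L)),
                     dosages(g))
})

test_that("partial copy noise puts within-block r2 between background and 1", {
    cfg <- simConfig(tree = list(S = list(F = 0.05, pops = c(A = 0.01))),
                     nPerPop = 60L, mSnps = 2000L, seed = 13L)
    fp <- simulateFrequencies(cfg)
    g <- simulateGenotypes(fp, cfg)
    gb <- injectLDBlocks(g, blockLen = 2L, noise = 0.5, seed = 3L,
                         panel = fp)
    d <- dosages(gb)
    within <- vapply(seq(1, 1999, by = 2), function(s)
        genotypeR2(d[s, ], d[s + 1, ]), numeric(1))
    across <- vapply(seq(2, 1998, by = 2), function(s)
        genotypeR2(d[s, ], d[s + 1, ]), numeric(1))
    expect_gt(mean(within), mean(across))
    expect_lt(mean(within), 1)
})

test_that("coordinate layouts behave as designed", {
    u <- assignCoordinates(100L, "uniform", chromLengthBp = 1e6)
    expect_true(all(diff(u$pos) == u$pos[1]))
    cl0 <- assignCoordinates(100L, "clustered", clusterSpan = 10000,
                             gapBp = 0, snpsPerCluster = 100L)
    expect_true(all(diff(cl0$pos) == diff(cl0$pos)[1]))
    cl <- assignCoordinates(500L, "clustered", clusterSpan = 10000,
                            gapBp = 500000, snpsPerCluster = 50L)
    closePairs <- function(pos) {
        dd <- abs(outer(pos, pos, "-"))
        mean(dd[upper.tri(dd)] <= 50000)
    }
    un <- assignCoordinates(500L, "uniform", chromLengthBp = 1e7)
    expect_gt(closePairs(cl$pos), 5 * closePairs(un$pos))
    expect_error(assignCoordinates(10L, "clustered", clusterSpan = 5,
                                   snpsPerCluster = 50L), "span")
})

test_that("AIM ascertainment enriches for differentiated sites", {
    cfg <- paperlikeConfig(nPerPop = 5L, mSnps = 4000L, seed = 6L)
    fp <- simulateFrequencies(cfg)
    score <- apply(fp@popFreq, 2, var)
    top <- which(score >= quantile(score, 0.9))
    allIn <- ascertainAims(fp, "maf_variance_top", fractionAims = 1,
                           nSites = 300L, seed = 2L)
    expect_true(all(allIn %in% top))
    expect_false(anyDuplicated(allIn) > 0)
    # resampling oracle: at 80% AIMs the selected sites carry more
    # across-population variance than a size-matched random draw
    hits <- 0L
    for (s in 1:100) {
        asc <- ascertainAims(fp, "maf_variance_top", fractionAims = 0.8,
                             nSites = 300L, seed = s)
        set.seed(s + 10000L)
        rnd <- sample(length(score), 300L)
        if (mean(score[asc]) > mean(score[rnd])) hits <- hits + 1L
    }
    expect_gte(hits, 95L)
    expect_error(ascertainAims(fp, nSites = 10 * cfg$mSnps), "available")
})

test_that("unascertained panels leave pairwise F_ST unbiased", {
    # with fractionAims = 0 the ascertained draw is a plain random draw;
    # over seeds the ascertained-minus-random F_ST difference has no
    # systematic sign
    signs <- vapply(1:10, function(s) {
        cfg <- twoSuperConfig(nPerPop = 20L, mSnps = 2000L, seed = s)
        fp <- simulateFrequencies(cfg)
        g <- simulatePanel(cfg)
        fr <- alleleFrequencies(g)
        asc <- ascertainAims(fp, fractionAims = 0, nSites = 600L,
                             seed = s + 500L)
        set.seed(s + 900L)
        rnd <- sort(sample(cfg$mSnps, 600L))
        fa <- hudsonFstPair(subsetFreqs(fr, asc), "A", "C", blocks = NULL)
        fb <- hudsonFstPair(subsetFreqs(fr, rnd), "A", "C", blocks = NULL)
        sign(fa@estimate - fb@estimate)
    }, numeric(1))
    expect_true(any(signs > 0) && any(signs < 0))
})

test_that("drift F near 0 everywhere gives F_ST consistent with 0", {
    cfg <- simConfig(tree = list(
        S1 = list(F = 1e-6, pops = c(A = 1e-6)),
        S2 = list(F = 1e-6, pops = c(B = 1e-6))),
        nPerPop = 50L, mSnps = 5000L, seed = 17L)
    g <- simulatePanel(cfg)
    r <- hudsonFstPair(alleleFrequencies(g), "A", "B")
    expect_lt(abs(r@estimate), 3 * r@se)
})
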