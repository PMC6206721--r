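# The brute-force jackknife oracle lives in helper-oracles.R.

test_that("allele frequencies count alleles per population", {
    g <- GenotypePanel(rbind(c(0L, 1L, 2L), c(0L, NA, 2L),
                             c(NA, NA, NA)),
                       chrom = "1", pos = c(10L, 20L, 30L),
                       samples = paste0("S", 1:3), population = "P")
    fr <- alleleFrequencies(g)
    expect_equal(unname(fr@freq["P", 1:2]), c(0.5, 0.5))
    expect_equal(unname(fr@nAlleles["P", ]), c(6, 4, 0))
    expect_true(is.na(fr@freq["P", 3]))
})

test_that("Hudson F_ST spans its definitional range", {
    # complete divergence
    div <- freqTable(rbind(A = c(0, 0), B = c(1, 1)), 20)
    expect_equal(hudsonFstPair(div, "A", "B", blocks = NULL)@estimate, 1)
    # panmixia in the large-sample limit
    p <- seq(0.1, 0.9, length.out = 50)
    same <- freqTable(rbind(A = p, B = p), 2e9)
    expect_equal(hudsonFstPair(same, "A", "B", blocks = NULL)@estimate, 0,
                 tolerance = 1e-6)
})

test_that("per-site Hudson estimator matches the hand-computed value", {
    ft <- freqTable(rbind(A = 0.2, B = 0.8), 20)
    est <- hudsonFstPair(ft, "A", "B", blocks = NULL)@estimate
    N <- 0.36 - 2 * (0.16 / 19); D <- 0.68
    expect_equal(est, N / D, tolerance = 1e-12)
    expect_equal(N / D, 0.504644, tolerance = 1e-6)
})

test_that("duplicated populations give F_ST consistent with zero", {
    cfg <- twoSuperConfig(nPerPop = 40L, mSnps = 4000L, seed = 23L)
    g <- simulatePanel(cfg)
    pops <- populations(g)
    idx <- which(pops == "A")
    half1 <- idx[seq_len(20)]; half2 <- idx[21:40]
    pops[half2] <- "A2"
    g2 <- GenotypePanel(dosages(g), chrom = siteChrom(g), pos = sitePos(g),
                        samples = colnames(g), population = pops)
    r <- hudsonFstPair(alleleFrequencies(g2), "A", "A2")
    expect_lt(abs(r@estimate), 3 * r@se)
})

test_that("F_ST matrix is symmetric, zero-diagonal, and tracks structure", {
    cfg <- twoSuperConfig(nPerPop = 25L, mSnps = 3000L, seed = 19L)
    fr <- alleleFrequencies(simulatePanel(cfg))
    M <- fstMatrix(fr)
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
    within <- c(M["A", "B"], M["C", "D"])
    between <- c(M["A", "C"], M["A", "D"], M["B", "C"], M["B", "D"])
    expect_gt(min(between), max(within))
})

test_that("f3 and f4 reproduce forced arithmetic in the infinite-n limit", {
    big <- 1e12
    expect_error(blockJackknife(1, 1, 1), "at least 2")
    ft <- freqTable(rbind(A = c(0.1, 0.1), B = c(0.9, 0.9),
                          C = c(0.5, 0.5)), big)
    expect_equal(f3(ft, "C", "A", "B", blocks = c(1, 2))@estimate, -0.16,
                 tolerance = 1e-6)
    ft2 <- freqTable(rbind(A = c(0.1, 0.3), B = c(0.9, 0.5),
                           C = c(0.5, 0.4)), big)
    expect_equal(f3(ft2, "C", "A", "B", blocks = c(1, 2))@estimate,
                 mean(c((0.5 - 0.1) * (0.5 - 0.9),
                        (0.4 - 0.3) * (0.4 - 0.5))), tolerance = 1e-6)
    same <- freqTable(rbind(A = c(0.2, 0.4), B = c(0.2, 0.4),
                            C = c(0.2, 0.4)), big)
    expect_equal(f3(same, "C", "A", "B", blocks = c(1, 2))@estimate, 0,
                 tolerance = 1e-6)
    f4t <- freqTable(rbind(A = c(0.9, 0.9), B = c(0.1, 0.1),
                           C = c(0.8, 0.8), D = c(0.2, 0.2)), 20)
    expect_equal(f4(f4t, "A", "B", "C", "D", blocks = c(1, 2))@estimate,
                 0.48)
    aEqB <- freqTable(rbind(A = c(0.3, 0.6), B = c(0.3, 0.6),
                            C = c(0.8, 0.2), D = c(0.2, 0.9)), 20)
    expect_identical(f4(aEqB, "A", "B", "C", "D",
                        blocks = c(1, 2))@estimate, 0)
})

test_that("f3/f4/F_ST agree with brute-force evaluation on a toy table", {
    set.seed(77)
    m <- 6L
    freq <- rbind(A = runif(m, 0.1, 0.9), B = runif(m, 0.1, 0.9),
                  C = runif(m, 0.1, 0.9))
    ft <- freqTable(freq, 20, pos = seq_len(m) * 10L)
    blocks <- c(1L, 1L, 2L, 2L, 3L, 3L)
    # brute-force f3
    tj <- (freq["C", ] - freq["A", ]) * (freq["C", ] - freq["B", ]) -
        freq["C", ] * (1 - freq["C", ]) / 19
    bf <- bruteJackknife(tj, rep(1, m), blocks)
    r <- f3(ft, "C", "A", "B", blocks = blocks)
    expect_equal(r@estimate, bf$estimate, tolerance = 1e-10)
    expect_equal(r@se, bf$se, tolerance = 1e-10)
    expect_equal(r@z, bf$estimate / bf$se, tolerance = 1e-10)
    # brute-force F_ST (ratio of averages as N/D weighted mean)
    p1 <- freq["A", ]; p2 <- freq["B", ]
    N <- (p1 - p2)^2 - p1 * (1 - p1) / 19 - p2 * (1 - p2) / 19
    D <- p1 * (1 - p2) + p2 * (1 - p1)
    bfF <- bruteJackknife(N / D, D, blocks)
    rf <- hudsonFstPair(ft, "A", "B", blocks = blocks)
    expect_equal(rf@estimate, sum(N) / sum(D), tolerance = 1e-12)
    expect_equal(rf@estimate, bfF$estimate, tolerance = 1e-12)
    expect_equal(rf@se, bfF$se, tolerance = 1e-10)
    # brute-force f4 on four populations
    freq4 <- rbind(freq, D = runif(m, 0.1, 0.9))
    ft4 <- freqTable(freq4, 20, pos = seq_len(m) * 10L)
    t4 <- (freq4["A", ] - freq4["B", ]) * (freq4["C", ] - freq4["D", ])
    bf4 <- bruteJackknife(t4, rep(1, m), blocks)
    r4 <- f4(ft4, "A", "B", "C", "D", blocks = blocks)
    expect_equal(r4@estimate, bf4$estimate, tolerance = 1e-10)
    expect_equal(r4@se, bf4$se, tolerance = 1e-10)
})

test_that("block jackknife closed forms", {
    # two equal blocks with constant values 1 and 3: estimate 2, SE 1
    v <- c(rep(1, 5), rep(3, 5)); w <- rep(1, 10)
    jk <- blockJackknife(v, w, rep(1:2, each = 5))
    expect_equal(jk$estimate, 2)
    expect_equal(jk$se, 1)
    # identical leave-one-out estimates -> SE 0, Z reported as +Inf
    ft <- freqTable(rbind(A = c(0.2, 0.2), B = c(0.8, 0.8)), 1e12)
    r <- hudsonFstPair(ft, "A", "B", blocks = c(1, 2))
    expect_equal(r@se, 0)
    expect_true(is.infinite(r@z) && r@z > 0)
})

test_that("jackknife SE tracks the analytic standard error for iid values", {
    ok <- 0L
    for (s in 1:20) {
        set.seed(s)
        v <- rnorm(500)
        jk <- blockJackknife(v, rep(1, 500), rep(1:25, each = 20))
        analytic <- sd(v) / sqrt(500)
        if (jk$se < 3 * analytic && analytic < 3 * jk$se) ok <- ok + 1L
    }
    expect_gte(ok, 19L)
})

test_that("f-statistic argument symmetries hold exactly", {
    set.seed(41)
    m <- 50L
    freq <- rbind(A = runif(m, 0.1, 0.9), B = runif(m, 0.1, 0.9),
                  C = runif(m, 0.1, 0.9), D = runif(m, 0.1, 0.9))
    ft <- freqTable(freq, 30, pos = seq_len(m) * 1e6L)
    blocks <- rep(1:5, each = 10)
    expect_equal(f3(ft, "C", "A", "B", blocks = blocks)@estimate,
                 f3(ft, "C", "B", "A", blocks = blocks)@estimate)
    fABCD <- f4(ft, "A", "B", "C", "D", blocks = blocks)
    expect_equal(fABCD@estimate,
                 -f4(ft, "B", "A", "C", "D", blocks = blocks)@estimate)
    expect_equal(fABCD@estimate,
                 f4(ft, "C", "D", "A", "B", blocks = blocks)@estimate)
    expect_equal(fABCD@se, f4(ft, "B", "A", "C", "D", blocks = blocks)@se)
})

test_that("f3 scans enumerate unordered triads once", {
    set.seed(2)
    freq3 <- matrix(runif(15, 0.2, 0.8), nrow = 3,
                    dimnames = list(c("A", "B", "C"), NULL))
    expect_identical(nrow(f3Scan(freqTable(freq3, 20),
                                 blocks = rep(1:2, length.out = 5))), 3L)
    freq5 <- matrix(runif(100, 0.2, 0.8), nrow = 5,
                    dimnames = list(LETTERS[1:5], NULL))
    sc <- f3Scan(freqTable(freq5, 20), blocks = rep(1:4, each = 5))
    expect_identical(nrow(sc), 30L)
    expect_false(any(duplicated(paste(sc$C, pmin(sc$A, sc$B),
                                      pmax(sc$A, sc$B)))))
})

test_that("Hudson and Weir-Cockerham estimators agree on balanced data", {
    cfg <- twoSuperConfig(nPerPop = 50L, mSnps = 3000L, seed = 29L)
    g <- simulatePanel(cfg)
    fr <- alleleFrequencies(g)
    h <- hudsonFstPair(fr, "A", "C")
    w <- weirFstPair(g, "A", "C")
    expect_equal(h@estimate, w@estimate, tolerance = 0.1)
})
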