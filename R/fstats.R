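#' Per-population allele frequencies and allele counts
#'
#' For every population and site: p = (sum of alternate dosages) /
#' (2 x non-missing individuals); the observed allele count n = 2 x
#' non-missing individuals is recorded alongside. Frequencies based on fewer
#' than 2 alleles are reported as NA (undefined).
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @return An \linkS4class{AlleleFrequencyTable}.
#' @export
alleleFrequencies <- function(g) {
    d <- dosages(g)
    pops <- populations(g)
    upop <- unique(pops)
    if (any(table(pops) == 0)) stop("population with zero samples")
    P <- vapply(upop, function(p) as.numeric(pops == p),
                numeric(length(pops)))
    dz <- d; dz[is.na(dz)] <- 0L
    obs <- !is.na(d)
    sumAlt <- dz %*% P
    nAll <- 2 * (obs %*% P)
    freq <- sumAlt / nAll
    freq[nAll < 2] <- NA_real_
    methods::new("AlleleFrequencyTable",
        freq = t(freq), nAlleles = t(nAll),
        chrom = siteChrom(g), pos = sitePos(g))
}

#' Subset an AlleleFrequencyTable by site index
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param idx integer (or logical) site indices.
#' @return the restricted \linkS4class{AlleleFrequencyTable}.
#' @export
subsetFreqs <- function(freqs, idx) {
    methods::new("AlleleFrequencyTable",
        freq = freqs@freq[, idx, drop = FALSE],
        nAlleles = freqs@nAlleles[, idx, drop = FALSE],
        chrom = freqs@chrom[idx], pos = freqs@pos[idx])
}

#' Assign contiguous jackknife blocks to the sites of a frequency table
#'
#' Default blocking: contiguous 5 Mb coordinate blocks per chromosome. When
#' that produces fewer than \code{minBlocks} blocks (e.g. a single short
#' chromosome), falls back to equal-count site blocks (up to 100).
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param blocksMb block extent in Mb (default 5).
#' @param minBlocks minimum acceptable block count before the equal-count
#'   fallback kicks in (default 5).
#' @return integer block assignment, one entry per site.
#' @export
assignBlocks <- function(freqs, blocksMb = 5, minBlocks = 5L) {
    key <- paste(freqs@chrom, freqs@pos %/% (blocksMb * 1e6))
    blocks <- match(key, unique(key))
    if (length(unique(blocks)) < minBlocks) {
        m <- length(freqs@pos)
        nb <- max(2L, min(100L, m %/% 2L))
        blocks <- as.integer(cut(seq_len(m), breaks = nb, labels = FALSE))
    }
    blocks
}

#' Weighted delete-one-block jackknife
#'
#' The overall estimate is the weighted mean of the per-site values; the
#' standard error comes from the weighted delete-one-block jackknife
#' (Busing-style), with block weights equal to the summed site weights. This
#' covers both plain means (unit weights) and ratio-of-sums estimators
#' (values N/D with weights D).
#'
#' @param values per-site values.
#' @param weights per-site nonnegative weights.
#' @param blocks per-site block assignment (at least 2 non-empty blocks).
#' @return list(estimate, se, nBlocks).
#' @export
blockJackknife <- function(values, weights, blocks) {
    stopifnot(length(values) == length(weights),
              length(values) == length(blocks))
    ub <- unique(blocks)
    B <- length(ub)
    if (B < 2L) stop("block jackknife needs at least 2 non-empty blocks")
    wTot <- sum(weights)
    sTot <- sum(values * weights)
    est <- sTot / wTot
    wB <- vapply(ub, function(b) sum(weights[blocks == b]), numeric(1))
    sB <- vapply(ub, function(b)
        sum((values * weights)[blocks == b]), numeric(1))
    thetaMinus <- (sTot - sB) / (wTot - wB)
    h <- wTot / wB
    tau <- h * est - (h - 1) * thetaMinus
    thetaJ <- B * est - sum((1 - wB / wTot) * thetaMinus)
    v <- sum((tau - thetaJ)^2 / (h - 1)) / B
    list(estimate = est, se = sqrt(v), nBlocks = B)
}

fstatResult <- function(statistic, pops, jk, nSnps) {
    z <- if (jk$se > 0) jk$estimate / jk$se
         else if (jk$estimate == 0) 0 else Inf * sign(jk$estimate)
    methods::new("FStatResult", statistic = statistic,
        populations = pops, estimate = jk$estimate, se = jk$se, z = z,
        nBlocks = as.integer(jk$nBlocks), nSnps = as.integer(nSnps))
}

#' Hudson's pairwise F_ST (ratio of averages)
#'
#' Per usable site (>= 2 observed alleles in both populations and not
#' monomorphic across the pair), with sample allele frequencies p1, p2 and
#' allele counts n1, n2:
#' N = (p1 - p2)^2 - p1(1 - p1)/(n1 - 1) - p2(1 - p2)/(n2 - 1),
#' D = p1(1 - p2) + p2(1 - p1).
#' The estimate is sum(N)/sum(D) (ratio of averages). Negative estimates are
#' reported as computed, never clamped. The jackknife operates on the same
#' ratio via values N/D weighted by D.
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param popA,popB population names.
#' @param blocks per-site block assignment, \code{"auto"} (default,
#'   \code{\link{assignBlocks}}) or \code{NULL} to skip the jackknife.
#' @return An \linkS4class{FStatResult} with statistic "fst".
#' @export
hudsonFstPair <- function(freqs, popA, popB, blocks = "auto") {
    p1 <- freqs@freq[popA, ]; p2 <- freqs@freq[popB, ]
    n1 <- freqs@nAlleles[popA, ]; n2 <- freqs@nAlleles[popB, ]
    use <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2 &
        !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
    if (!any(use)) stop("no usable sites for F_ST between ", popA,
                        " and ", popB)
    p1 <- p1[use]; p2 <- p2[use]; n1 <- n1[use]; n2 <- n2[use]
    N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    D <- p1 * (1 - p2) + p2 * (1 - p1)
    if (identical(blocks, "auto")) blocks <- assignBlocks(freqs)[use]
    else if (!is.null(blocks)) blocks <- blocks[use]
    if (is.null(blocks)) {
        jk <- list(estimate = sum(N) / sum(D), se = NA_real_,
                   nBlocks = 0L)
        z <- NA_real_
        return(methods::new("FStatResult", statistic = "fst",
            populations = c(popA, popB), estimate = jk$estimate,
            se = jk$se, z = z, nBlocks = 0L, nSnps = sum(use)))
    }
    jk <- blockJackknife(N / D, D, blocks)
    fstatResult("fst", c(popA, popB), jk, sum(use))
}

#' Pairwise F_ST matrix
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param pops populations to include (default all rows of \code{freqs}).
#' @param blocks jackknife blocking, as in \code{\link{hudsonFstPair}}.
#' @return symmetric matrix of Hudson F_ST estimates with zero diagonal.
#' @export
fstMatrix <- function(freqs, pops = rownames(freqs@freq), blocks = "auto") {
    if (length(pops) < 2L) stop("need at least 2 populations")
    M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)[-length(pops)])
        for (j in seq.int(i + 1L, length(pops))) {
            est <- hudsonFstPair(freqs, pops[i], pops[j],
                                 blocks = blocks)@estimate
            M[i, j] <- M[j, i] <- est
        }
    M
}

#' f3-statistic f3(C; A, B) with block jackknife
#'
#' Per usable site with population frequencies a, b, c and allele count n_C:
#' t = (c - a)(c - b) - c(1 - c)/(n_C - 1), the second term being the
#' unbiased correction for the sampling heterozygosity of the target C. The
#' estimate is the mean of t over usable sites; SE and Z come from the
#' weighted block jackknife. A significantly negative value indicates that C
#' is admixed between sources related to A and B.
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param C,A,B population names (target first).
#' @param blocks per-site block assignment or \code{"auto"}.
#' @param normalize divide by the sampling-corrected heterozygosity of C
#'   (ratio of sums); off by default since the raw sign and magnitude are
#'   interpreted.
#' @return An \linkS4class{FStatResult} with statistic "f3".
#' @export
f3 <- function(freqs, C, A, B, blocks = "auto", normalize = FALSE) {
    a <- freqs@freq[A, ]; b <- freqs@freq[B, ]; cc <- freqs@freq[C, ]
    nc <- freqs@nAlleles[C, ]
    use <- !is.na(a) & !is.na(b) & !is.na(cc) & nc >= 2
    if (!any(use)) stop("no usable sites for f3")
    a <- a[use]; b <- b[use]; cc <- cc[use]; nc <- nc[use]
    t <- (cc - a) * (cc - b) - cc * (1 - cc) / (nc - 1)
    if (identical(blocks, "auto")) blocks <- assignBlocks(freqs)[use]
    else blocks <- blocks[use]
    if (normalize) {
        h <- 2 * cc * (1 - cc) * nc / (nc - 1)
        keep <- h > 0
        jk <- blockJackknife((t / h)[keep], h[keep], blocks[keep])
        return(fstatResult("f3", c(C, A, B), jk, sum(keep)))
    }
    jk <- blockJackknife(t, rep(1, length(t)), blocks)
    fstatResult("f3", c(C, A, B), jk, sum(use))
}

#' f4-statistic f4(A, B; C, D) with block jackknife
#'
#' Per usable site t = (a - b)(c - d); no bias correction is needed. Under a
#' correct tree ((A,B),(C,D)) with no gene flow the expectation is zero.
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param A,B,C,D four distinct population names.
#' @param blocks per-site block assignment or \code{"auto"}.
#' @return An \linkS4class{FStatResult} with statistic "f4".
#' @export
f4 <- function(freqs, A, B, C, D, blocks = "auto") {
    if (anyDuplicated(c(A, B, C, D)))
        stop("f4 needs four distinct populations")
    a <- freqs@freq[A, ]; b <- freqs@freq[B, ]
    cc <- freqs@freq[C, ]; d <- freqs@freq[D, ]
    use <- !is.na(a) & !is.na(b) & !is.na(cc) & !is.na(d)
    if (!any(use)) stop("no usable sites for f4")
    t <- ((a - b) * (cc - d))[use]
    if (identical(blocks, "auto")) blocks <- assignBlocks(freqs)[use]
    else blocks <- blocks[use]
    jk <- blockJackknife(t, rep(1, length(t)), blocks)
    fstatResult("f4", c(A, B, C, D), jk, sum(use))
}

#' f3 over all (or given) population triads
#'
#' One row per triad (C; A, B) with A/B unordered; the symmetric duplicate
#' (C; B, A) is not emitted.
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param triads optional data.frame/matrix with columns C, A, B; default all
#'   triads over the populations of \code{freqs}.
#' @param blocks jackknife blocking, as in \code{\link{f3}}.
#' @return data.frame with columns C, A, B, estimate, se, z, nSnps, nBlocks.
#' @export
f3Scan <- function(freqs, triads = NULL, blocks = "auto") {
    if (is.null(triads)) {
        pops <- rownames(freqs@freq)
        triads <- do.call(rbind, lapply(pops, function(C) {
            others <- setdiff(pops, C)
            if (length(others) < 2L) return(NULL)
            ab <- t(utils::combn(others, 2L))
            data.frame(C = C, A = ab[, 1L], B = ab[, 2L])
        }))
    }
    triads <- as.data.frame(triads)
    if (identical(blocks, "auto")) blocks <- assignBlocks(freqs)
    res <- lapply(seq_len(nrow(triads)), function(i) {
        r <- f3(freqs, triads$C[i], triads$A[i], triads$B[i],
                blocks = blocks)
        data.frame(C = triads$C[i], A = triads$A[i], B = triads$B[i],
                   estimate = r@estimate, se = r@se, z = r@z,
                   nSnps = r@nSnps, nBlocks = r@nBlocks)
    })
    do.call(rbind, res)
}

#' Weir-Cockerham pairwise F_ST (alternative estimator)
#'
#' The two-population Weir-Cockerham (1984) theta with ratio-of-sums
#' combination, computed from genotype data (it needs the observed
#' heterozygote proportions, which a frequency table does not carry).
#' Offered as a cross-check for \code{\link{hudsonFstPair}}; the estimators
#' agree in the large-sample limit but weight sample sizes differently.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param popA,popB population names.
#' @param blocks per-site block assignment or \code{"auto"}.
#' @return An \linkS4class{FStatResult} with statistic "fst".
#' @export
weirFstPair <- function(g, popA, popB, blocks = "auto") {
    d <- dosages(g)
    pops <- populations(g)
    dA <- d[, pops == popA, drop = FALSE]
    dB <- d[, pops == popB, drop = FALSE]
    n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
    p1 <- rowSums(dA, na.rm = TRUE) / (2 * n1)
    p2 <- rowSums(dB, na.rm = TRUE) / (2 * n2)
    h1 <- rowSums(dA == 1, na.rm = TRUE) / n1
    h2 <- rowSums(dB == 1, na.rm = TRUE) / n2
    use <- n1 >= 1 & n2 >= 1 &
        !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
    if (!any(use)) stop("no usable sites")
    n1 <- n1[use]; n2 <- n2[use]; p1 <- p1[use]; p2 <- p2[use]
    h1 <- h1[use]; h2 <- h2[use]
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    aComp <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    bComp <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) /
         (4 * nbar))
    cComp <- hbar / 2
    num <- aComp
    den <- aComp + bComp + cComp
    ok <- is.finite(num) & is.finite(den) & den != 0
    freqs <- alleleFrequencies(g)
    if (identical(blocks, "auto")) blocks <- assignBlocks(freqs)[use][ok]
    else if (!is.null(blocks)) blocks <- blocks[use][ok]
    jk <- blockJackknife((num / den)[ok], den[ok], blocks)
    fstatResult("fst", c(popA, popB), jk, sum(ok))
}
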