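#' Simulation configuration for structured-population genotype data
#'
#' Describes a two-level population hierarchy (super-populations containing
#' populations) with a Balding-Nichols drift parameter F on every branch,
#' optional admixed groups, an LD-block overlay and a coordinate layout.
#' Defaults follow the package's "paperlike" study design (see
#' \code{\link{paperlikeConfig}}).
#'
#' @param tree named list of super-populations. Each element is
#'   \code{list(F = <branch drift>, pops = c(popName = <branch drift>, ...))}.
#'   All drift parameters must lie strictly in (0, 1).
#' @param nPerPop individuals per population (including admixed groups).
#' @param mSnps number of simulated SNP sites.
#' @param ancestralMafRange interval within (0, 0.5] from which ancestral
#'   alternate-allele frequencies are drawn uniformly. The default floor of
#'   0.05 keeps most sites polymorphic; monomorphic leaf sites can still arise
#'   by drift and are handled downstream.
#' @param admixture list of admixed groups, each
#'   \code{list(target = "X", sources = c("A", "B"), props = c(0.7, 0.3))};
#'   sources must be leaf populations, proportions nonnegative and summing
#'   to 1.
#' @param ldBlock \code{NULL} or \code{list(blockLen = , noise = )} applied by
#'   \code{\link{injectLDBlocks}}.
#' @param layout coordinate layout, \code{"uniform"} or \code{"clustered"}.
#' @param layoutParams parameters for \code{\link{assignCoordinates}}.
#' @param missingRate per-entry probability of a missing genotype.
#' @param seed root seed; per-operation child streams are derived from it
#'   deterministically (see \code{childSeed}).
#' @return A validated object of class \code{SimConfig} (a named list).
#' @export
simConfig <- function(tree, nPerPop = 30L, mSnps = 20000L,
                      ancestralMafRange = c(0.05, 0.5),
                      admixture = list(), ldBlock = NULL,
                      layout = c("uniform", "clustered"),
                      layoutParams = list(), missingRate = 0,
                      seed = 1L) {
    layout <- match.arg(layout)
    if (!is.list(tree) || is.null(names(tree)) || any(names(tree) == ""))
        stop("tree must be a named list of super-populations")
    leafF <- unlist(lapply(tree, function(sp) sp$pops))
    allF <- c(vapply(tree, function(sp) sp$F, numeric(1)), leafF)
    if (any(allF <= 0) || any(allF >= 1))
        stop("all drift parameters must lie strictly in (0, 1)")
    leaves <- unlist(lapply(tree, function(sp) names(sp$pops)))
    if (anyDuplicated(leaves))
        stop("population names must be unique across super-populations")
    if (nPerPop < 1L || mSnps < 1L)
        stop("nPerPop and mSnps must be at least 1")
    if (length(ancestralMafRange) != 2L || ancestralMafRange[1] <= 0 ||
        ancestralMafRange[2] > 0.5 ||
        ancestralMafRange[1] > ancestralMafRange[2])
        stop("ancestralMafRange must be an interval within (0, 0.5]")
    for (ad in admixture) {
        if (!all(c("target", "sources", "props") %in% names(ad)))
            stop("each admixture spec needs target, sources and props")
        if (!all(ad$sources %in% leaves))
            stop("admixture source not in tree: ",
                 paste(setdiff(ad$sources, leaves), collapse = ", "))
        if (any(ad$props < 0) || abs(sum(ad$props) - 1) > 1e-8)
            stop("mixing proportions must be nonnegative and sum to 1")
    }
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    structure(list(tree = tree, nPerPop = as.integer(nPerPop),
                   mSnps = as.integer(mSnps),
                   ancestralMafRange = ancestralMafRange,
                   admixture = admixture, ldBlock = ldBlock,
                   layout = layout, layoutParams = layoutParams,
                   missingRate = missingRate, seed = as.integer(seed)),
              class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
    leaves <- unlist(lapply(x$tree, function(sp) names(sp$pops)))
    cat(sprintf(
        "SimConfig: %d super-populations, %d populations, %d admixed group(s)\n",
        length(x$tree), length(leaves), length(x$admixture)))
    cat(sprintf("  n = %d per population, m = %d SNPs, layout %s, seed %d\n",
        x$nPerPop, x$mSnps, x$layout, x$seed))
    invisible(x)
}

#' The package's default study design
#'
#' Five super-populations of three populations each (mirroring a
#' continental-scale sample collection), with between-super-population branch
#' drift F = 0.08 and within-super-population drift F = 0.01, 30 individuals
#' per population, 20,000 SNPs, and one 70/30 admixed group drawing from two
#' different super-populations. Runs end-to-end in well under a minute while
#' showing the ascertainment effects the package studies.
#'
#' @param nPerPop,mSnps,seed overrides for scaled-down runs.
#' @param ... further arguments passed to \code{\link{simConfig}}.
#' @return A \code{SimConfig}.
#' @export
paperlikeConfig <- function(nPerPop = 30L, mSnps = 20000L, seed = 1L, ...) {
    sps <- paste0("SP", 1:5)
    tree <- lapply(sps, function(sp) {
        pops <- setNames(rep(0.01, 3), paste0(sp, letters[1:3]))
        list(F = 0.08, pops = pops)
    })
    names(tree) <- sps
    simConfig(tree = tree, nPerPop = nPerPop, mSnps = mSnps,
              admixture = list(list(target = "ADMX",
                                    sources = c("SP1a", "SP2a"),
                                    props = c(0.7, 0.3))),
              seed = seed, ...)
}

# Deterministic child seed for a named sub-stream of the root seed.
# Keeps results reproducible while decoupling the draws of the different
# simulation stages. Always below 2^31 - 1.
childSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# One Balding-Nichols drift step: child frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
# (mean p, variance p(1-p)F). Fixed parents stay fixed.
bnDraw <- function(p, F) {
    out <- p
    idx <- which(p > 0 & p < 1)
    if (length(idx)) {
        a <- p[idx] * (1 - F) / F
        b <- (1 - p[idx]) * (1 - F) / F
        out[idx] <- rbeta(length(idx), a, b)
    }
    out
}

#' Simulate per-population allele frequencies down a drift tree
#'
#' Ancestral frequencies are drawn uniformly from the configured range; each
#' branch applies a Balding-Nichols Beta draw with that branch's drift
#' parameter F, so the expected child frequency equals the parent frequency
#' and the added variance is p(1-p)F.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{FrequencyPanel} with one row per leaf population.
#' @export
simulateFrequencies <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(childSeed(config$seed, "frequencies"))
    m <- config$mSnps
    anc <- runif(m, config$ancestralMafRange[1], config$ancestralMafRange[2])
    rows <- list()
    for (sp in names(config$tree)) {
        node <- config$tree[[sp]]
        pSup <- bnDraw(anc, node$F)
        for (pop in names(node$pops))
            rows[[pop]] <- bnDraw(pSup, node$pops[[pop]])
    }
    popFreq <- do.call(rbind, rows)
    methods::new("FrequencyPanel", ancestral = anc, popFreq = popFreq)
}

#' Simulate diploid genotypes from a FrequencyPanel
#'
#' Unadmixed individuals draw dosages Binomial(2, p_pop) per site. An admixed
#' individual draws each of its two allele copies independently from source
#' population k with probability equal to k's mixing proportion, which makes
#' the dosage Binomial(2, sum_k prop_k p_k). Coordinates are attached with
#' \code{\link{assignCoordinates}} and LD blocks injected with
#' \code{\link{injectLDBlocks}} when configured.
#'
#' @param panel a \linkS4class{FrequencyPanel} covering every population
#'   referenced by \code{config} (including admixture sources).
#' @param config the \code{\link{simConfig}} used to generate \code{panel}.
#' @return A \linkS4class{GenotypePanel}.
#' @export
simulateGenotypes <- function(panel, config) {
    stopifnot(methods::is(panel, "FrequencyPanel"),
              inherits(config, "SimConfig"))
    leaves <- rownames(panel@popFreq)
    for (ad in config$admixture)
        if (!all(ad$sources %in% leaves))
            stop("admixture source not in tree: ",
                 paste(setdiff(ad$sources, leaves), collapse = ", "))
    set.seed(childSeed(config$seed, "genotypes"))
    m <- ncol(panel@popFreq)
    n <- config$nPerPop
    groups <- c(as.list(setNames(leaves, leaves)),
                setNames(lapply(config$admixture, identity),
                         vapply(config$admixture, `[[`, "", "target")))
    cols <- list(); labs <- character(0)
    for (gname in names(groups)) {
        gdef <- groups[[gname]]
        freq <- if (is.character(gdef)) panel@popFreq[gdef, ]
                else drop(gdef$props %*% panel@popFreq[gdef$sources, ,
                                                       drop = FALSE])
        g <- matrix(rbinom(m * n, 2L, rep(freq, n)), nrow = m, ncol = n)
        cols[[gname]] <- g
        labs <- c(labs, rep(gname, n))
    }
    dosage <- do.call(cbind, cols)
    if (config$missingRate > 0) {
        drop <- runif(length(dosage)) < config$missingRate
        dosage[drop] <- NA_integer_
    }
    samples <- unlist(lapply(names(groups),
                             function(g) paste0(g, "_", seq_len(n))))
    colnames(dosage) <- samples
    coords <- do.call(assignCoordinates,
        c(list(mSnps = m, layout = config$layout,
               seed = childSeed(config$seed, "coords")),
          config$layoutParams))
    gp <- GenotypePanel(dosage, chrom = coords$chrom, pos = coords$pos,
                        samples = samples, population = labs)
    if (!is.null(config$ldBlock))
        gp <- injectLDBlocks(gp, config$ldBlock$blockLen,
                             config$ldBlock$noise,
                             seed = childSeed(config$seed, "ldblocks"),
                             panel = panel)
    gp
}

#' Simulate a full GenotypePanel in one call
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{GenotypePanel}.
#' @export
simulatePanel <- function(config) {
    simulateGenotypes(simulateFrequencies(config), config)
}

#' Overlay blocks of linked markers on a genotype panel
#'
#' Within every consecutive run of \code{blockLen} sites, sites 2..blockLen
#' are replaced by copies of the block's first genotype column; each copied
#' entry is then, independently with probability \code{noise}, resampled from
#' the individual's population frequency at its own site. \code{noise = 0}
#' gives blocks in complete LD; \code{noise = 1} leaves the distribution of
#' the matrix unchanged.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param blockLen sites per block (>= 1; 1 is the identity).
#' @param noise per-entry resampling probability in [0, 1].
#' @param seed integer seed.
#' @param panel optional \linkS4class{FrequencyPanel} supplying the true
#'   population frequencies; when absent, empirical per-population frequencies
#'   estimated from \code{g} are used.
#' @return A \linkS4class{GenotypePanel} of identical shape.
#' @export
injectLDBlocks <- function(g, blockLen, noise, seed = 1L, panel = NULL) {
    stopifnot(blockLen >= 1, noise >= 0, noise <= 1)
    if (blockLen == 1L) return(g)
    d <- dosages(g)
    pops <- populations(g)
    if (is.null(panel)) {
        freqs <- alleleFrequencies(g)
        popFreq <- freqs@freq
        popFreq[is.na(popFreq)] <- 0
    } else popFreq <- panel@popFreq
    set.seed(seed)
    m <- nrow(d); n <- ncol(d)
    popIdx <- match(pops, rownames(popFreq))
    # admixed groups absent from the frequency panel: use their empirical freq
    if (anyNA(popIdx)) {
        extra <- unique(pops[is.na(popIdx)])
        emp <- t(vapply(extra, function(p)
            rowMeans(d[, pops == p, drop = FALSE], na.rm = TRUE) / 2,
            numeric(m)))
        popFreq <- rbind(popFreq, emp)
        popIdx <- match(pops, rownames(popFreq))
    }
    starts <- seq(1L, m, by = blockLen)
    for (s in starts) {
        e <- min(s + blockLen - 1L, m)
        if (e == s) next
        anchor <- d[s, ]
        for (j in (s + 1L):e) {
            col <- anchor
            res <- runif(n) < noise
            if (any(res)) {
                pj <- popFreq[popIdx[res], j]
                col[res] <- rbinom(sum(res), 2L, pj)
            }
            d[j, ] <- col
        }
    }
    SummarizedExperiment::assay(g, "dosage") <- d
    g
}

#' Assign genomic coordinates to simulated sites
#'
#' \code{"uniform"} spaces sites evenly along synthetic chromosomes;
#' \code{"clustered"} packs them into gene-like clusters of \code{clusterSpan}
#' bp separated by \code{gapBp} bp, emulating the exon-dense organisation of
#' coding regions. Positions are strictly increasing per chromosome.
#'
#' @param mSnps number of sites.
#' @param layout \code{"uniform"} or \code{"clustered"}.
#' @param nChrom synthetic chromosomes; sites are split as evenly as possible.
#' @param chromLengthBp chromosome length for the uniform layout.
#' @param clusterSpan,gapBp,snpsPerCluster clustered-layout geometry.
#' @param seed unused at present (layouts are deterministic); kept so layout
#'   variants with randomised placement can be added without interface change.
#' @return list(chrom = character, pos = integer), usable directly in
#'   \code{\link{GenotypePanel}}.
#' @export
assignCoordinates <- function(mSnps, layout = c("uniform", "clustered"),
                              nChrom = 1L, chromLengthBp = 100e6,
                              clusterSpan = 10000, gapBp = 500000,
                              snpsPerCluster = 50L, seed = 1L) {
    layout <- match.arg(layout)
    per <- diff(floor(seq(0, mSnps, length.out = nChrom + 1L)))
    chrom <- rep(as.character(seq_len(nChrom)), per)
    pos <- integer(0)
    for (ci in seq_len(nChrom)) {
        mc <- per[ci]
        if (mc == 0L) next
        if (layout == "uniform") {
            spacing <- max(1L, floor(chromLengthBp / mc))
            pos <- c(pos, spacing * seq_len(mc))
        } else {
            if (clusterSpan < snpsPerCluster)
                stop("cluster span shorter than the SNPs it must hold")
            within <- max(1L, floor(clusterSpan / snpsPerCluster))
            idx <- seq_len(mc) - 1L
            clu <- idx %/% snpsPerCluster
            off <- idx %% snpsPerCluster
            pos <- c(pos, as.integer(clu * (clusterSpan + gapBp) +
                                     off * within + 1L))
        }
    }
    list(chrom = chrom, pos = as.integer(pos))
}

#' Ascertain an AIM-enriched site list
#'
#' Emulates array-style marker pre-selection: a \code{fractionAims} share of
#' the requested sites is drawn from the top decile of a differentiation
#' ranking (across-population variance of allele frequency, or |p_A - p_B|
#' for a named population pair), the remainder uniformly at random from the
#' other sites. \code{fractionAims = 0} is an unbiased random panel drawn
#' through the same generator path.
#'
#' @param panel a \linkS4class{FrequencyPanel}.
#' @param mode \code{"maf_variance_top"} or \code{"delta_pair"}.
#' @param fractionAims share of AIMs in the panel, in [0, 1].
#' @param nSites panel size.
#' @param pair two population names (for \code{mode = "delta_pair"}).
#' @param seed integer seed.
#' @return Sorted integer site indices into \code{panel}, without duplicates.
#' @export
ascertainAims <- function(panel, mode = c("maf_variance_top", "delta_pair"),
                          fractionAims = 0.8, nSites, pair = NULL,
                          seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(fractionAims >= 0, fractionAims <= 1)
    m <- ncol(panel@popFreq)
    if (nSites > m)
        stop(sprintf("requested %d sites but only %d available", nSites, m))
    score <- if (mode == "maf_variance_top") {
        apply(panel@popFreq, 2L, var)
    } else {
        if (is.null(pair) || length(pair) != 2L)
            stop("mode 'delta_pair' needs two population names in 'pair'")
        abs(panel@popFreq[pair[1], ] - panel@popFreq[pair[2], ])
    }
    decile <- which(score >= quantile(score, 0.9))
    nTop <- round(fractionAims * nSites)
    if (nTop > length(decile))
        stop("not enough top-decile sites for the requested AIM fraction")
    set.seed(seed)
    selTop <- if (nTop > 0) sample(decile, nTop) else integer(0)
    rest <- setdiff(seq_len(m), selTop)
    selRest <- sample(rest, nSites - nTop)
    sort(c(selTop, selRest))
}
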