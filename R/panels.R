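#' GRCh37 autosome lengths
#'
#' The 22 standard GRCh37/hg19 autosome lengths in base pairs, named "1".."22".
#' Used as the default chromosome set for \code{\link{genomeSchemeRegions}}.
#'
#' @return named numeric vector of length 22.
#' @export
grch37AutosomeLengths <- function() {
    c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
      `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
      `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
      `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
      `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
      `21` = 48129895, `22` = 51304566)
}

#' Dispersed genome-style region scheme
#'
#' Builds the homogeneously dispersed coordinate list used for a whole-genome
#' style SNP panel: on every chromosome the first and last
#' \code{telomereExcl} bp are excluded, the remaining span is tiled into
#' consecutive full stretches of \code{stretch} bp (a trailing partial
#' stretch is discarded), and each stretch contributes its first \code{take}
#' bp as one region. With the default parameters on the GRCh37 autosomes the
#' cumulative region size is 68.7 Mb, comparable to a high-quality exome
#' target.
#'
#' @param chromLengths named vector of chromosome lengths in bp; default the
#'   GRCh37 autosomes.
#' @param telomereExcl bp excluded at each chromosome end (default 5 Mb).
#' @param stretch tiling stretch length in bp (default 10 kb).
#' @param take bp taken from the start of each stretch (default 258).
#' @return A \code{GRanges} of disjoint, sorted regions, each of width
#'   \code{take}. Chromosomes shorter than \code{2 * telomereExcl} contribute
#'   nothing.
#' @export
genomeSchemeRegions <- function(chromLengths = grch37AutosomeLengths(),
                                telomereExcl = 5e6, stretch = 1e4,
                                take = 258) {
    stopifnot(take <= stretch, all(chromLengths > 0))
    chroms <- names(chromLengths)
    if (is.null(chroms)) chroms <- as.character(seq_along(chromLengths))
    allChrom <- character(0); allStart0 <- numeric(0)
    for (i in seq_along(chromLengths)) {
        span <- chromLengths[i] - 2 * telomereExcl
        if (span < stretch) next
        n <- floor(span / stretch)
        allChrom <- c(allChrom, rep(chroms[i], n))
        allStart0 <- c(allStart0, telomereExcl + (seq_len(n) - 1) * stretch)
    }
    if (!length(allChrom)) return(GenomicRanges::GRanges())
    GenomicRanges::sort(GenomicRanges::GRanges(allChrom,
        IRanges::IRanges(start = allStart0 + 1, width = take)))
}

#' Read a per-region coverage summary table
#'
#' @param path TSV with columns chrom, start, end (0-based half-open),
#'   min_coverage, mapq0_reads; a header row is tolerated.
#' @return data.frame with those five columns.
#' @export
readCoverageSummary <- function(path) {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(raw) && is.na(suppressWarnings(as.numeric(raw[1, 2]))))
        raw <- raw[-1, , drop = FALSE]
    df <- data.frame(chrom = as.character(raw[[1]]),
                     start = as.integer(raw[[2]]),
                     end = as.integer(raw[[3]]),
                     minCoverage = as.numeric(raw[[4]]),
                     mapq0Reads = as.numeric(raw[[5]]))
    if (any(df$minCoverage < 0) || any(df$mapq0Reads < 0))
        stop("coverage summary counts must be nonnegative")
    df
}

#' Keep high-coverage, uniquely mappable regions
#'
#' Region QC for sequencing-derived panels: a region is kept only when the
#' minimum coverage across all cohort samples is strictly greater than
#' \code{minCov} and its count of MAPQ0 reads (reads mappable to multiple
#' genomic locations) does not exceed \code{maxMapq0}. Sex chromosomes are
#' removed when \code{excludeSex}.
#'
#' @param cov a coverage summary data.frame
#'   (see \code{\link{readCoverageSummary}}).
#' @param minCov coverage threshold, strict (default 10, i.e. ">10x").
#' @param maxMapq0 maximum tolerated MAPQ0 reads (default 0: any such read
#'   disqualifies the region).
#' @param excludeSex drop X/Y regions (default TRUE).
#' @return A normalised \code{GRanges}.
#' @export
qualifyRegions <- function(cov, minCov = 10, maxMapq0 = 0,
                           excludeSex = TRUE) {
    keep <- cov$minCoverage > minCov & cov$mapq0Reads <= maxMapq0
    if (excludeSex) keep <- keep & !isSexChrom(cov$chrom)
    cov <- cov[keep, , drop = FALSE]
    if (!nrow(cov)) return(GenomicRanges::GRanges())
    regionSet(cov$chrom, cov$start, cov$end)
}

#' Subset a panel to the sites inside a region set
#'
#' A site at 1-based position p is kept when some interval (0-based half-open
#' [start, end)) satisfies start < p <= end. Site order is preserved; samples
#' and dosages are untouched.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param rs a \code{GRanges} region set (normalised internally).
#' @return A \linkS4class{GenotypePanel}.
#' @export
intersectVariants <- function(g, rs) {
    if (!length(rs)) return(g[integer(0), ])
    rs <- normalizeRegions(rs)
    hits <- GenomicRanges::findOverlaps(
        SummarizedExperiment::rowRanges(g), rs, type = "within")
    subsetSites(g, sort(unique(S4Vectors::queryHits(hits))))
}

#' Subset a panel to an explicit site list
#'
#' Sites are matched by (chromosome, position) only; allele identity is not
#' required, as array manifests may report strand-flipped alleles.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param sites data.frame with columns \code{chrom} and \code{pos} (1-based),
#'   e.g. from \code{\link{readSiteList}}.
#' @return A \linkS4class{GenotypePanel}.
#' @export
selectSites <- function(g, sites) {
    key <- paste(siteChrom(g), sitePos(g))
    want <- paste(as.character(sites$chrom), as.integer(sites$pos))
    subsetSites(g, which(key %in% want))
}

#' Remove rare and near-fixed variants by carrier count
#'
#' Keeps only sites where BOTH alleles are carried by at least
#' \code{minIndividuals} individuals: the alternate allele by samples with
#' dosage > 0 and the reference allele by samples with dosage < 2 (missing
#' genotypes excluded). The symmetric reference-side condition removes
#' near-fixed alternate sites that typically reflect reference-sequence
#' errors.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param minIndividuals carrier threshold (default 10).
#' @return A \linkS4class{GenotypePanel}.
#' @export
filterCarriers <- function(g, minIndividuals = 10) {
    d <- dosages(g)
    altCarriers <- rowSums(d > 0, na.rm = TRUE)
    refCarriers <- rowSums(d < 2, na.rm = TRUE)
    subsetSites(g, which(altCarriers >= minIndividuals &
                         refCarriers >= minIndividuals))
}

#' Per-site genotype QC statistics
#'
#' Computes, per site, the genotype counts, allele carrier counts, and the
#' site inbreeding coefficient F = 1 - observed het rate / expected het rate,
#' with expected heterozygosity 2*p*(1-p) from the non-missing allele
#' frequency estimate. Monomorphic sites (expected heterozygosity 0) are
#' assigned F = 0. Strongly negative F flags an excess of heterozygotes, the
#' signature of technical artefacts violating Hardy-Weinberg equilibrium in
#' a cohort of unrelated individuals.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @return A \code{DataFrame} with columns \code{homRef}, \code{het},
#'   \code{homAlt}, \code{carriersAlt}, \code{carriersRef}, \code{pHat},
#'   \code{fSite}, one row per site.
#' @export
siteQCStats <- function(g) {
    d <- dosages(g)
    nObs <- rowSums(!is.na(d))
    homRef <- rowSums(d == 0, na.rm = TRUE)
    het <- rowSums(d == 1, na.rm = TRUE)
    homAlt <- rowSums(d == 2, na.rm = TRUE)
    pHat <- ifelse(nObs > 0, rowSums(d, na.rm = TRUE) / (2 * nObs), NA_real_)
    expHet <- 2 * pHat * (1 - pHat)
    obsHet <- ifelse(nObs > 0, het / nObs, NA_real_)
    fSite <- ifelse(is.na(expHet) | expHet == 0, 0, 1 - obsHet / expHet)
    S4Vectors::DataFrame(homRef = homRef, het = het, homAlt = homAlt,
        carriersAlt = het + homAlt, carriersRef = homRef + het,
        pHat = pHat, fSite = fSite, row.names = rownames(d))
}

#' Drop sites with excess heterozygosity
#'
#' Removes sites whose inbreeding coefficient (\code{\link{siteQCStats}}) is
#' below \code{minF}; the default -0.5 removes only gross het-excess
#' artefacts.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param minF inbreeding coefficient lower bound (default -0.5).
#' @return A \linkS4class{GenotypePanel}.
#' @export
filterInbreeding <- function(g, minF = -0.5) {
    qc <- siteQCStats(g)
    subsetSites(g, which(qc$fSite >= minF))
}
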