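#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowRanges
#' @importFrom stats cor var sd rbinom runif rbeta rgamma setNames complete.cases quantile density pnorm
#' @importFrom utils read.table write.table head tail
NULL

#' GenotypePanel: diploid SNP genotypes with coordinates and population labels
#'
#' The central data container of the package. It extends
#' \linkS4class{RangedSummarizedExperiment}: the single assay \code{"dosage"}
#' holds the alternate-allele dosage (integer 0/1/2, \code{NA} for missing)
#' with one row per biallelic SNP and one column per sample; \code{rowRanges}
#' carries the site coordinates (1-based positions, width-1 ranges) together
#' with \code{ref}, \code{alt} and \code{id} metadata columns; \code{colData}
#' carries the mandatory \code{population} label of every sample.
#'
#' Validity requires: dosages in \{0,1,2,NA\}; single-nucleotide \code{ref}
#' and \code{alt} with \code{ref != alt}; strictly increasing positions within
#' each chromosome; exactly one population label per sample.
#'
#' @seealso \code{\link{GenotypePanel}} (constructor),
#'   \code{\link{dosages}}, \code{\link{populations}}
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
    msg <- character()
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% 0:2))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    if (!("population" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must contain a 'population' column")
    else if (anyNA(SummarizedExperiment::colData(object)$population))
        msg <- c(msg, "every sample needs a population label")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        mc <- S4Vectors::mcols(rr)
        if (!all(c("ref", "alt") %in% colnames(mc)))
            msg <- c(msg, "rowRanges needs 'ref' and 'alt' metadata columns")
        else {
            if (any(nchar(mc$ref) != 1L) || any(nchar(mc$alt) != 1L))
                msg <- c(msg, "ref and alt must be single bases")
            if (any(mc$ref == mc$alt))
                msg <- c(msg, "ref must differ from alt")
        }
        pos <- GenomicRanges::start(rr)
        chr <- as.character(GenomicRanges::seqnames(rr))
        for (cc in unique(chr)) {
            p <- pos[chr == cc]
            if (is.unsorted(p, strictly = TRUE)) {
                msg <- c(msg, sprintf(
                    "positions on chromosome %s must be strictly increasing", cc))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' FrequencyPanel: ancestral and per-population allele frequencies
#'
#' Output of \code{\link{simulateFrequencies}}. \code{popFreq} has one row per
#' leaf population of the simulated population tree and one column per site;
#' \code{ancestral} holds the root frequency of each site.
#'
#' @slot ancestral numeric vector of ancestral alternate-allele frequencies.
#' @slot popFreq population x site matrix of frequencies in [0, 1].
#' @export
setClass("FrequencyPanel",
    representation(ancestral = "numeric", popFreq = "matrix"))

setValidity("FrequencyPanel", function(object) {
    if (any(object@popFreq < 0) || any(object@popFreq > 1))
        return("population frequencies must lie in [0, 1]")
    if (ncol(object@popFreq) != length(object@ancestral))
        return("popFreq must have one column per ancestral frequency")
    if (is.null(rownames(object@popFreq)))
        return("popFreq rows must be named by population")
    TRUE
})

#' AlleleFrequencyTable: per-population alternate-allele frequencies
#'
#' @slot freq population x site matrix of alternate-allele frequencies
#'   (NA where fewer than 2 alleles were observed).
#' @slot nAlleles population x site matrix of observed allele counts
#'   (2 x non-missing individuals).
#' @slot chrom,pos site coordinates, used to assign jackknife blocks.
#' @export
setClass("AlleleFrequencyTable",
    representation(freq = "matrix", nAlleles = "matrix",
                   chrom = "character", pos = "integer"))

#' FStatResult: one f3/f4/F_ST estimate with jackknife uncertainty
#'
#' @slot statistic "f3", "f4" or "fst".
#' @slot populations populations in role order (C;A,B for f3; A,B;C,D for f4).
#' @slot estimate point estimate.
#' @slot se weighted block-jackknife standard error.
#' @slot z estimate / se (+Inf when se is 0).
#' @slot nBlocks,nSnps number of jackknife blocks and usable SNPs.
#' @export
setClass("FStatResult",
    representation(statistic = "character", populations = "character",
                   estimate = "numeric", se = "numeric", z = "numeric",
                   nBlocks = "integer", nSnps = "integer"))

setMethod("show", "FStatResult", function(object) {
    roles <- switch(object@statistic,
        f3 = sprintf("(%s; %s, %s)", object@populations[1],
                     object@populations[2], object@populations[3]),
        f4 = sprintf("(%s, %s; %s, %s)", object@populations[1],
                     object@populations[2], object@populations[3],
                     object@populations[4]),
        sprintf("(%s)", paste(object@populations, collapse = " vs ")))
    cat(sprintf("%s%s: estimate %.6g, SE %.3g, Z %.3g (%d SNPs, %d blocks)\n",
        object@statistic, roles, object@estimate, object@se, object@z,
        object@nSnps, object@nBlocks))
})

#' PruneResult: outcome of windowed greedy LD pruning
#'
#' @slot kept,pruned site identifiers (row names of the input panel), kept in
#'   input order; disjoint, union equals the input sites.
#' @slot params list(windowKb, stepSnps, r2Thresh).
#' @slot fractionPruned number pruned / number input.
#' @export
setClass("PruneResult",
    representation(kept = "character", pruned = "character",
                   params = "list", fractionPruned = "numeric"))

setMethod("show", "PruneResult", function(object) {
    cat(sprintf(
        "LD pruning: %d kept / %d pruned (%.1f%% pruned; window %g kb, step %d, r2 > %g)\n",
        length(object@kept), length(object@pruned),
        100 * object@fractionPruned, object@params$windowKb,
        object@params$stepSnps, object@params$r2Thresh))
})

#' PCAResult: Patterson-normalised principal components
#'
#' @slot eigenvalues descending eigenvalues of the sample covariance of the
#'   normalised genotype matrix.
#' @slot eigenvectors sample x component matrix, unit-norm columns.
#' @slot removedOutliers list of character vectors, one per removal iteration.
#' @slot nSitesUsed polymorphic sites entering the decomposition.
#' @export
setClass("PCAResult",
    representation(eigenvalues = "numeric", eigenvectors = "matrix",
                   removedOutliers = "list", nSitesUsed = "integer"))

setMethod("show", "PCAResult", function(object) {
    cat(sprintf("PCA: %d samples x %d components over %d sites\n",
        nrow(object@eigenvectors), ncol(object@eigenvectors),
        object@nSitesUsed))
    cat("  leading eigenvalues:",
        paste(signif(head(object@eigenvalues, 5), 4), collapse = ", "), "\n")
    nrm <- sum(lengths(object@removedOutliers))
    if (nrm) cat(sprintf("  %d outlier(s) removed over %d iteration(s)\n",
                         nrm, length(object@removedOutliers)))
})

#' AdmixtureFit: maximum-likelihood ancestry model for one K
#'
#' @slot Q sample x K ancestry fractions (rows sum to 1).
#' @slot F K x site component allele frequencies, clamped to [1e-6, 1-1e-6].
#' @slot loglik final log-likelihood.
#' @slot K number of ancestral components.
#' @slot nIter EM iterations run.
#' @slot converged TRUE when the log-likelihood increment fell below tol.
#' @slot seed seed used for the random initialisation.
#' @slot loglikTrace per-iteration log-likelihood values.
#' @export
setClass("AdmixtureFit",
    representation(Q = "matrix", F = "matrix", loglik = "numeric",
                   K = "integer", nIter = "integer", converged = "logical",
                   seed = "integer", loglikTrace = "numeric"))

setMethod("show", "AdmixtureFit", function(object) {
    cat(sprintf("Admixture fit: K = %d, %d samples, %d sites, loglik %.2f (%s after %d iterations)\n",
        object@K, nrow(object@Q), ncol(object@F), object@loglik,
        if (object@converged) "converged" else "not converged", object@nIter))
})

#' CVCurve: cross-validation error across candidate K
#'
#' @slot K candidate component counts.
#' @slot meanError mean masked-entry squared prediction error per K.
#' @slot foldErrors K x fold matrix of per-fold errors.
#' @slot bestK argmin of meanError (ties -> smaller K).
#' @slot relativeError meanError divided by the error of the worst-fitting
#'   (highest-error) K, so the reference K reads exactly 1.
#' @export
setClass("CVCurve",
    representation(K = "integer", meanError = "numeric", foldErrors = "matrix",
                   bestK = "integer", relativeError = "numeric"))

setMethod("show", "CVCurve", function(object) {
    cat("Cross-validation curve:\n")
    print(data.frame(K = object@K, meanError = object@meanError,
                     relativeError = object@relativeError))
    cat(sprintf("best K = %d\n", object@bestK))
})

#' PanelComparison: cross-panel summaries against a reference panel
#'
#' @slot panels names of the compared panels; \code{reference} is one of them.
#' @slot reference name of the reference panel.
#' @slot fstDifference list (per non-reference panel) of F_ST difference
#'   matrices, panel minus reference.
#' @slot f3Correlation Pearson r between matched triad-wise f3 vectors of
#'   each panel and the reference.
#' @slot eigenvalueRatio leading-eigenvalue ratio, panel / reference.
#' @slot cvCurves named list of relative CV curves (may be empty).
#' @slot fstMatrices named list of the underlying F_ST matrices.
#' @slot f3Tables named list of the underlying triad f3 tables.
#' @export
setClass("PanelComparison",
    representation(panels = "character", reference = "character",
                   fstDifference = "list", f3Correlation = "numeric",
                   eigenvalueRatio = "numeric", cvCurves = "list",
                   fstMatrices = "list", f3Tables = "list"))

setMethod("show", "PanelComparison", function(object) {
    cat(sprintf("Panel comparison vs reference '%s':\n", object@reference))
    for (p in setdiff(object@panels, object@reference)) {
        cat(sprintf("  %s: f3 correlation r = %.4f, leading-eigenvalue ratio %.3f\n",
            p, object@f3Correlation[[p]], object@eigenvalueRatio[[p]]))
    }
})
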