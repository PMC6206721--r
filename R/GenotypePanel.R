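#' Construct a GenotypePanel
#'
#' @param dosage integer matrix of alternate-allele dosages (0/1/2, NA for
#'   missing), sites in rows, samples in columns.
#' @param chrom,pos site coordinates (chromosome label, 1-based position).
#' @param ref,alt single-base reference and alternate alleles; defaults "A"/"G"
#'   are adequate for simulated data.
#' @param id site identifiers; default \code{chrom:pos}.
#' @param samples sample identifiers; default from \code{colnames(dosage)} or
#'   \code{S1..Sn}.
#' @param population population label per sample (recycled scalar allowed).
#' @return A \linkS4class{GenotypePanel}. Sites are sorted by (chromosome,
#'   position); chromosome order follows first appearance.
#' @examples
#' gp <- GenotypePanel(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                     chrom = c("1", "1"), pos = c(100L, 200L),
#'                     population = c("A", "B"))
#' dosages(gp)
#' @export
GenotypePanel <- function(dosage, chrom, pos, ref = "A", alt = "G",
                          id = NULL, samples = NULL, population) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    m <- nrow(dosage); n <- ncol(dosage)
    chrom <- as.character(rep_len(chrom, m))
    pos <- as.integer(rep_len(pos, m))
    ref <- rep_len(as.character(ref), m)
    alt <- rep_len(as.character(alt), m)
    if (is.null(id)) id <- paste0(chrom, ":", pos)
    if (is.null(samples))
        samples <- if (!is.null(colnames(dosage))) colnames(dosage)
                   else paste0("S", seq_len(n))
    population <- as.character(rep_len(population, n))
    ord <- order(match(chrom, unique(chrom)), pos)
    gr <- GenomicRanges::GRanges(chrom[ord],
        IRanges::IRanges(pos[ord], width = 1L),
        ref = ref[ord], alt = alt[ord], id = id[ord])
    names(gr) <- id[ord]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage[ord, , drop = FALSE]),
        rowRanges = gr,
        colData = S4Vectors::DataFrame(population = population,
                                       row.names = samples))
    methods::new("GenotypePanel", se)
}

#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Accessors for GenotypePanel
#'
#' \code{dosages} returns the site x sample dosage matrix; \code{populations}
#' the per-sample population labels (named by sample); \code{siteChrom} /
#' \code{sitePos} the coordinates; \code{nSites} / \code{nSamples} the
#' dimensions.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @return See description.
#' @export
setMethod("dosages", "GenotypePanel", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname dosages
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname dosages
#' @export
setMethod("populations", "GenotypePanel", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$population),
             colnames(x)))

#' @rdname dosages
#' @export
siteChrom <- function(x)
    as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))

#' @rdname dosages
#' @export
sitePos <- function(x)
    GenomicRanges::start(SummarizedExperiment::rowRanges(x))

#' @rdname dosages
#' @export
nSites <- function(x) nrow(x)

#' @rdname dosages
#' @export
nSamples <- function(x) ncol(x)

setMethod("show", "GenotypePanel", function(object) {
    pops <- populations(object)
    cat(sprintf("GenotypePanel: %d SNPs x %d samples, %d population(s)\n",
        nrow(object), ncol(object), length(unique(pops))))
    tb <- table(pops)
    cat("  populations:",
        paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
    miss <- mean(is.na(dosages(object)))
    if (miss > 0) cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
})

# internal: subset sites by row index, preserving class
subsetSites <- function(g, idx) {
    g[idx, ]
}
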