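#' Read a multi-sample VCF into a GenotypePanel
#'
#' Parsing is delegated to \code{VariantAnnotation::readVcf}; this function
#' applies the variant-level filters of the data model: multi-allelic records
#' are always dropped (with a reported count), non-SNP records are dropped
#' when \code{snpsOnly}, records whose FILTER is neither PASS nor missing are
#' dropped when \code{passOnly}, and sex chromosomes are dropped when
#' \code{excludeSex}. Phased and unphased genotypes are treated identically;
#' half-calls and missing calls become \code{NA}.
#'
#' @param path path to a VCF (v4.x) file with GT fields.
#' @param passOnly drop records failing FILTER (default TRUE).
#' @param snpsOnly keep only single-nucleotide biallelic records (default
#'   TRUE).
#' @param excludeSex drop chromosomes labelled X, Y, chrX or chrY (default
#'   TRUE).
#' @param popLabels named character vector (sample -> population) or path to a
#'   two-column TSV as read by \code{\link{readPopLabels}}. Every sample in
#'   the VCF must be labelled; missing samples raise an error naming them.
#' @return A \linkS4class{GenotypePanel}.
#' @export
readGenotypeVcf <- function(path, passOnly = TRUE, snpsOnly = TRUE,
                            excludeSex = TRUE, popLabels = NULL) {
    v <- VariantAnnotation::readVcf(path, genome = "unknown")
    if (!("GT" %in% rownames(VariantAnnotation::geno(
            VariantAnnotation::header(v)))))
        stop("VCF has no GT format field: ", path)
    nMulti <- sum(S4Vectors::elementNROWS(VariantAnnotation::alt(v)) > 1L)
    keep <- S4Vectors::elementNROWS(VariantAnnotation::alt(v)) == 1L
    if (nMulti > 0)
        message(nMulti, " multi-allelic record(s) dropped")
    v <- v[keep, ]
    ref <- as.character(VariantAnnotation::ref(v))
    alt <- as.character(unlist(VariantAnnotation::alt(v)))
    if (snpsOnly) {
        snp <- nchar(ref) == 1L & nchar(alt) == 1L &
            ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
        v <- v[snp, ]; ref <- ref[snp]; alt <- alt[snp]
    }
    if (passOnly) {
        filt <- VariantAnnotation::fixed(v)$FILTER
        ok <- is.na(filt) | filt %in% c("PASS", ".")
        v <- v[ok, ]; ref <- ref[ok]; alt <- alt[ok]
    }
    chrom <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(v)))
    if (excludeSex) {
        aut <- !isSexChrom(chrom)
        v <- v[aut, ]; ref <- ref[aut]; alt <- alt[aut]
        chrom <- chrom[aut]
    }
    gt <- VariantAnnotation::geno(v)$GT
    dosage <- gtToDosage(gt)
    samples <- colnames(gt)
    if (is.character(popLabels) && length(popLabels) == 1L &&
        file.exists(popLabels))
        popLabels <- readPopLabels(popLabels)
    if (is.null(popLabels)) {
        pops <- rep("unlabeled", length(samples))
    } else {
        missing <- setdiff(samples, names(popLabels))
        if (length(missing))
            stop("samples without population label: ",
                 paste(missing, collapse = ", "))
        pops <- unname(popLabels[samples])
    }
    ids <- names(SummarizedExperiment::rowRanges(v))
    if (is.null(ids)) ids <- paste0(chrom, ":",
        GenomicRanges::start(SummarizedExperiment::rowRanges(v)))
    GenotypePanel(dosage,
        chrom = chrom,
        pos = GenomicRanges::start(SummarizedExperiment::rowRanges(v)),
        ref = ref, alt = alt, id = ids, samples = samples,
        population = pops)
}

# GT string matrix -> dosage; phase separators unified, half-calls missing
gtToDosage <- function(gt) {
    u <- gsub("|", "/", gt, fixed = TRUE)
    d <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
    d[u %in% c("0/0", "0")] <- 0L
    d[u %in% c("0/1", "1/0")] <- 1L
    d[u %in% c("1/1", "1")] <- 2L
    d
}

#' Write a GenotypePanel as VCF
#'
#' Emits a minimal VCF v4 with unphased GT genotypes via
#' \code{VariantAnnotation::writeVcf}. Round-tripping through
#' \code{\link{readGenotypeVcf}} preserves dosages, site order and ids.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param path output path (plain-text \code{.vcf}).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(g, path) {
    d <- dosages(g)
    gt <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
    rr <- SummarizedExperiment::rowRanges(g)
    mc <- S4Vectors::mcols(rr)
    vr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rr),
                                 IRanges::ranges(rr))
    names(vr) <- mc$id
    hdr <- VariantAnnotation::VCFHeader(
        samples = colnames(g),
        header = IRanges::DataFrameList(
            fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                              row.names = "fileformat"),
            FORMAT = S4Vectors::DataFrame(Number = "1", Type = "String",
                Description = "Genotype", row.names = "GT")))
    fx <- S4Vectors::DataFrame(
        REF = Biostrings::DNAStringSet(mc$ref),
        ALT = Biostrings::DNAStringSetList(as.list(mc$alt)),
        QUAL = rep(NA_real_, length(vr)),
        FILTER = rep("PASS", length(vr)))
    vcf <- VariantAnnotation::VCF(rowRanges = vr,
        colData = S4Vectors::DataFrame(Samples = seq_len(ncol(g)),
                                       row.names = colnames(g)),
        exptData = list(header = hdr),
        fixed = fx,
        geno = S4Vectors::SimpleList(GT = gt))
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}

isSexChrom <- function(chrom) chrom %in% c("X", "Y", "chrX", "chrY")

#' Region sets: construction, normalisation and BED round trip
#'
#' Regions are held as \code{GRanges} (1-based, closed) but all BED text uses
#' the 0-based half-open convention, so the file line \code{"chr1 99 100"}
#' becomes the single 1-based position 100. \code{normalizeRegions} sorts and
#' merges overlapping or adjacent intervals; readers normalise on entry.
#'
#' @param chrom,start,end vectors in BED convention (0-based half-open).
#' @return \code{regionSet}, \code{readBedRegions}: a normalised
#'   \code{GRanges}. \code{writeBedRegions}: the path, invisibly.
#' @export
regionSet <- function(chrom, start, end) {
    if (any(start >= end))
        stop("malformed region: start must be < end (0-based half-open)")
    gr <- GenomicRanges::GRanges(as.character(chrom),
        IRanges::IRanges(start = as.integer(start) + 1L,
                         end = as.integer(end)))
    normalizeRegions(gr)
}

#' @rdname regionSet
#' @param rs a \code{GRanges} region set.
#' @export
normalizeRegions <- function(rs) {
    GenomicRanges::reduce(GenomicRanges::sort(rs))
}

#' @rdname regionSet
#' @param path path to a 3+ column tab-separated BED file.
#' @export
readBedRegions <- function(path) {
    gr <- rtracklayer::import(rtracklayer::BEDFile(path))
    if (any(GenomicRanges::width(gr) < 1L))
        stop("malformed region in ", path,
             ": start must be < end (0-based half-open)")
    S4Vectors::mcols(gr) <- NULL
    normalizeRegions(gr)
}

#' @rdname regionSet
#' @export
writeBedRegions <- function(rs, path) {
    rtracklayer::export(rs, rtracklayer::BEDFile(path))
    invisible(path)
}

#' Read a two-column site list (chrom, 1-based position)
#'
#' Duplicate rows are collapsed.
#'
#' @param path TSV path; a header line is tolerated when its position column
#'   is non-numeric.
#' @return data.frame with columns \code{chrom}, \code{pos}.
#' @export
readSiteList <- function(path) {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(raw) && is.na(suppressWarnings(as.integer(raw[1, 2]))))
        raw <- raw[-1, , drop = FALSE]
    df <- unique(data.frame(chrom = as.character(raw[[1]]),
                            pos = as.integer(raw[[2]])))
    rownames(df) <- NULL
    df
}

#' Read a two-column sample-to-population label table
#'
#' @param path TSV path (sample, population).
#' @return named character vector, sample -> population.
#' @export
readPopLabels <- function(path) {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    setNames(as.character(raw[[2]]), as.character(raw[[1]]))
}

#' @rdname readPopLabels
#' @param labels named character vector (sample -> population).
#' @export
writePopLabels <- function(labels, path) {
    write.table(data.frame(names(labels), unname(labels)), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Export a GenotypePanel in PED/MAP format
#'
#' Space-separated, one line per sample: family id (the population), sample
#' id, zero parental/sex/phenotype fields, then two allele letters per site.
#' Dosage fidelity is guaranteed; dialect details beyond that are not.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param prefix output prefix; writes \code{prefix.ped} and
#'   \code{prefix.map}.
#' @return character vector of the two paths, invisibly.
#' @export
exportPedMap <- function(g, prefix) {
    d <- dosages(g)
    rr <- SummarizedExperiment::rowRanges(g)
    mc <- S4Vectors::mcols(rr)
    mapPath <- paste0(prefix, ".map"); pedPath <- paste0(prefix, ".ped")
    write.table(data.frame(siteChrom(g), mc$id, 0L, sitePos(g)),
                mapPath, sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    pops <- populations(g)
    allelePairs <- function(dos, ref, alt) {
        a1 <- ifelse(is.na(dos), "0", ifelse(dos >= 1, alt, ref))
        a2 <- ifelse(is.na(dos), "0", ifelse(dos == 2, alt, ref))
        paste(a1, a2)
    }
    lines <- vapply(seq_len(ncol(d)), function(i) {
        paste(pops[i], colnames(d)[i], 0, 0, 0, -9,
              paste(allelePairs(d[, i], mc$ref, mc$alt), collapse = " "))
    }, character(1))
    writeLines(lines, pedPath)
    invisible(c(pedPath, mapPath))
}
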