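#' Per-SNP across-population minor-allele-frequency variance
#'
#' The ascertainment diagnostic: for every site the minor allele is defined
#' on the pooled sample (the allele with pooled frequency <= 0.5; ties go to
#' the alternate allele), each population's frequency of that same allele is
#' taken, and their sample variance (denominator nPops - 1) is reported.
#' Panels enriched for ancestry-informative markers show a right-shifted
#' variance distribution relative to unascertained panels of the same size.
#' Sites with fewer than 2 populations with defined frequencies are skipped
#' with a reported count.
#'
#' @param freqs an \linkS4class{AlleleFrequencyTable}.
#' @param popVariance use the population variance (denominator nPops)
#'   instead of the sample variance (default FALSE).
#' @return A \code{DataFrame} with columns \code{chrom}, \code{pos},
#'   \code{nPops}, \code{mafVariance} and a matrix column \code{popMAF}
#'   (per-population frequency of the pooled minor allele).
#' @export
mafVariance <- function(freqs, popVariance = FALSE) {
    p <- freqs@freq; n <- freqs@nAlleles
    nPops <- colSums(!is.na(p) & n >= 2)
    usable <- nPops >= 2L
    if (any(!usable))
        message(sum(!usable),
                " site(s) skipped (fewer than 2 populations with data)")
    pw <- p; pw[is.na(pw)] <- 0
    nw <- n; nw[is.na(p)] <- 0
    pooled <- colSums(pw * nw) / colSums(nw)
    flip <- pooled > 0.5                # minor allele is ref there; tie -> alt
    maf <- p
    maf[, flip] <- 1 - maf[, flip]
    center <- colMeans(maf, na.rm = TRUE)
    dev2 <- sweep(maf, 2L, center, `-`)^2
    denom <- if (popVariance) nPops else nPops - 1L
    v <- colSums(dev2, na.rm = TRUE) / denom
    v[!usable] <- NA_real_
    S4Vectors::DataFrame(chrom = freqs@chrom, pos = freqs@pos,
        nPops = nPops, mafVariance = v, popMAF = I(t(maf)))
}

#' Compare panels against a reference panel
#'
#' Takes one result bundle per panel - \code{list(fst = <FstMatrix>,
#' f3 = <f3Scan table>, eigenvalues = <numeric>, cv = <CVCurve or NULL>)} -
#' and summarises each non-reference panel against the reference:
#' elementwise F_ST differences (panel minus reference), the Pearson
#' correlation between matched triad-wise f3 vectors, the
#' leading-eigenvalue ratio, and the relative CV curves aligned on the
#' shared K range.
#'
#' @param panelResults named list of result bundles.
#' @param reference name of the reference panel (must be in
#'   \code{panelResults}).
#' @return A \linkS4class{PanelComparison}.
#' @export
comparePanels <- function(panelResults, reference) {
    stopifnot(length(panelResults) >= 2L,
              !is.null(names(panelResults)))
    if (!reference %in% names(panelResults))
        stop("reference panel '", reference, "' not among panels")
    ref <- panelResults[[reference]]
    refPops <- rownames(ref$fst)
    fstDiff <- list(); f3Cor <- numeric(0); evRatio <- numeric(0)
    cvCurves <- list(); fstMats <- list(); f3Tabs <- list()
    for (nm in names(panelResults)) {
        pr <- panelResults[[nm]]
        pops <- rownames(pr$fst)
        if (!setequal(pops, refPops))
            stop("population sets differ between '", nm, "' and reference: ",
                 paste(c(setdiff(pops, refPops), setdiff(refPops, pops)),
                       collapse = ", "))
        fstMats[[nm]] <- pr$fst[refPops, refPops]
        f3Tabs[[nm]] <- pr$f3
        if (!is.null(pr$cv))
            cvCurves[[nm]] <- data.frame(K = pr$cv@K,
                relativeError = pr$cv@relativeError)
        if (nm == reference) next
        fstDiff[[nm]] <- fstMats[[nm]] - ref$fst[refPops, refPops]
        key <- function(t) paste(t$C, pmin(t$A, t$B), pmax(t$A, t$B))
        idx <- match(key(ref$f3), key(pr$f3))
        if (anyNA(idx)) stop("triad lists differ between '", nm,
                             "' and reference")
        f3Cor[[nm]] <- cor(ref$f3$estimate, pr$f3$estimate[idx])
        evRatio[[nm]] <- pr$eigenvalues[1] / ref$eigenvalues[1]
    }
    methods::new("PanelComparison", panels = names(panelResults),
        reference = reference, fstDifference = fstDiff,
        f3Correlation = f3Cor, eigenvalueRatio = evRatio,
        cvCurves = cvCurves, fstMatrices = fstMats, f3Tables = f3Tabs)
}

#' Write comparison tables, plots and run metadata
#'
#' Writes, with deterministic file names into \code{outDir}: one F_ST matrix
#' TSV per panel (\code{fst_<panel>.tsv}), one difference matrix per
#' non-reference panel (\code{fst_diff_<panel>.tsv}), the triad f3 tables
#' (\code{f3_<panel>.tsv}), a cross-panel summary
#' (\code{panel_summary.tsv}: f3 correlation and eigenvalue ratio), relative
#' CV curves when present (\code{cv_curves.tsv}), a run-metadata JSON
#' (\code{run_metadata.json}), and illustrative PNG plots (f3 scatter vs
#' reference; MAF-variance density when \code{mafVar} is supplied; PCA
#' scatter when \code{pca} is supplied; stacked ancestry bars when
#' \code{admixture} is supplied). Reruns with identical inputs produce
#' byte-identical TSVs.
#'
#' @param comparison a populated \linkS4class{PanelComparison}.
#' @param outDir output directory (created if needed).
#' @param mafVar optional named list of \code{\link{mafVariance}} tables.
#' @param pca optional named list of \linkS4class{PCAResult} objects with a
#'   \code{populations} attribute for colouring.
#' @param admixture optional named list of \linkS4class{AdmixtureFit}.
#' @param metadata list merged into the run-metadata JSON (seeds,
#'   parameters).
#' @return character vector of the files written, invisibly.
#' @export
reportComparison <- function(comparison, outDir, mafVar = NULL, pca = NULL,
                             admixture = NULL, metadata = list()) {
    if (!length(comparison@panels)) stop("empty comparison, nothing written")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
    written <- character(0)
    wTsv <- function(df, name, rn = FALSE) {
        path <- file.path(outDir, name)
        write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                    row.names = rn, col.names = TRUE)
        written <<- c(written, path)
    }
    for (nm in comparison@panels) {
        wTsv(comparison@fstMatrices[[nm]], paste0("fst_", nm, ".tsv"),
             rn = TRUE)
        wTsv(comparison@f3Tables[[nm]], paste0("f3_", nm, ".tsv"))
    }
    for (nm in names(comparison@fstDifference))
        wTsv(comparison@fstDifference[[nm]],
             paste0("fst_diff_", nm, ".tsv"), rn = TRUE)
    others <- setdiff(comparison@panels, comparison@reference)
    wTsv(data.frame(panel = others,
                    f3Correlation = comparison@f3Correlation[others],
                    eigenvalueRatio = comparison@eigenvalueRatio[others]),
         "panel_summary.tsv")
    if (length(comparison@cvCurves)) {
        cv <- do.call(rbind, lapply(names(comparison@cvCurves), function(nm)
            cbind(panel = nm, comparison@cvCurves[[nm]])))
        wTsv(cv, "cv_curves.tsv")
    }
    meta <- c(list(package = "panelbias",
                   version = as.character(utils::packageVersion("panelbias")),
                   reference = comparison@reference,
                   panels = comparison@panels,
                   mafVarianceDenominator = "nPops - 1 (sample variance)",
                   densityBandwidth = "stats::bw.nrd0"),
              metadata)
    metaPath <- file.path(outDir, "run_metadata.json")
    jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, metaPath)
    # illustrative plots; all assertions elsewhere run on the numbers
    ref <- comparison@reference
    pngPath <- file.path(outDir, "f3_scatter.png")
    grDevices::png(pngPath, width = 700, height = 700)
    refF3 <- comparison@f3Tables[[ref]]
    key <- function(t) paste(t$C, pmin(t$A, t$B), pmax(t$A, t$B))
    plot(NA, xlim = range(refF3$estimate), ylim = range(unlist(
            lapply(comparison@f3Tables, function(t) t$estimate))),
         xlab = paste("f3,", ref), ylab = "f3, other panels",
         main = "Triad-wise f3 against the reference panel")
    cols <- seq_along(others) + 1L
    for (i in seq_along(others)) {
        t <- comparison@f3Tables[[others[i]]]
        graphics::points(refF3$estimate, t$estimate[match(key(refF3),
                                                          key(t))],
                         col = cols[i], pch = 20)
    }
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", legend = others, col = cols, pch = 20)
    grDevices::dev.off()
    written <- c(written, pngPath)
    if (!is.null(mafVar)) {
        p <- file.path(outDir, "maf_variance_density.png")
        grDevices::png(p, width = 700, height = 500)
        dens <- lapply(mafVar, function(t)
            density(t$mafVariance[!is.na(t$mafVariance)]))
        plot(NA, xlim = range(unlist(lapply(dens, `[[`, "x"))),
             ylim = range(unlist(lapply(dens, `[[`, "y"))),
             xlab = "across-population MAF variance", ylab = "density",
             main = "MAF-variance density per panel")
        for (i in seq_along(dens))
            graphics::lines(dens[[i]], col = i + 1L)
        graphics::legend("topright", legend = names(mafVar),
                         col = seq_along(dens) + 1L, lty = 1)
        grDevices::dev.off()
        written <- c(written, p)
        summ <- data.frame(panel = names(mafVar),
            meanMafVariance = vapply(mafVar, function(t)
                mean(t$mafVariance, na.rm = TRUE), numeric(1)))
        wTsv(summ, "maf_variance_summary.tsv")
    }
    if (!is.null(pca)) {
        for (nm in names(pca)) {
            p <- file.path(outDir, paste0("pca_", nm, ".png"))
            grDevices::png(p, width = 700, height = 700)
            vec <- pca[[nm]]@eigenvectors
            pop <- attr(pca[[nm]], "populations")
            col <- if (is.null(pop)) 1L else as.integer(factor(pop))
            plot(vec[, 1], vec[, 2], col = col, pch = 20,
                 xlab = "PC1", ylab = "PC2",
                 main = paste("PCA,", nm))
            grDevices::dev.off()
            written <- c(written, p)
        }
    }
    if (!is.null(admixture)) {
        for (nm in names(admixture)) {
            p <- file.path(outDir, paste0("admixture_", nm, ".png"))
            grDevices::png(p, width = 900, height = 400)
            graphics::barplot(t(admixture[[nm]]@Q), border = NA,
                space = 0, col = seq_len(admixture[[nm]]@K) + 1L,
                main = paste0("Ancestry fractions (K = ",
                              admixture[[nm]]@K, "), ", nm),
                ylab = "ancestry fraction")
            grDevices::dev.off()
            written <- c(written, p)
        }
    }
    invisible(written)
}
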