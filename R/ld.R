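#' Squared genotype correlation between two dosage vectors
#'
#' Composite (genotype-level) LD: the squared Pearson correlation of the two
#' dosage vectors over their pairwise non-missing entries. Either vector
#' being constant yields 0 by convention; fewer than 2 complete pairs yields
#' 0 with a warning.
#'
#' @param x,y equal-length dosage vectors (NA = missing).
#' @return r-squared in [0, 1].
#' @export
genotypeR2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) {
        warning("fewer than 2 complete pairs; r2 undefined, returning 0")
        return(0)
    }
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) return(0)
    unname(cor(x, y)^2)
}

# r2 matrix for a dosage block (sites x samples); constant/short pairs -> 0
r2Matrix <- function(d) {
    r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
    r[!is.finite(r)] <- 0
    r^2
}

#' Windowed greedy pairwise LD pruning
#'
#' Reproduces the indep-pairwise protocol on dosage data. Per chromosome, a
#' window is the maximal run of still-unpruned SNPs whose positions lie
#' within \code{windowKb} kb of the window's first SNP. Within a window,
#' while any remaining pair has r-squared above \code{r2Thresh}, the
#' first such pair in scan order is taken and one member pruned: the one
#' with the lower pooled minor-allele frequency, ties resolved against the
#' later-positioned SNP. The window start then advances by \code{stepSnps}
#' positions in the remaining-SNP order; a SNP pruned anywhere stays pruned.
#' The procedure is deterministic and the result does not depend on the
#' chromosome processing order.
#'
#' Monomorphic sites carry no LD information and are pruned up front with a
#' reported count.
#'
#' @param g a \linkS4class{GenotypePanel} with coordinate-sorted sites (the
#'   class guarantees this).
#' @param windowKb window extent in kb of physical position (default 10,000
#'   kb, the extended window appropriate for clustered exome-like panels;
#'   50 kb is the conventional choice for dispersed panels).
#' @param stepSnps window increment in SNPs (default 10).
#' @param r2Thresh pruning threshold (default 0.1).
#' @return A \linkS4class{PruneResult}.
#' @export
indepPairwise <- function(g, windowKb = 10000, stepSnps = 10,
                          r2Thresh = 0.1) {
    stopifnot(windowKb > 0, stepSnps >= 1, r2Thresh >= 0)
    d <- dosages(g)
    ids <- rownames(d)
    chrom <- siteChrom(g); pos <- sitePos(g)
    p <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p, na.rm = TRUE)
    mono <- apply(d, 1L, function(x) {
        x <- x[!is.na(x)]
        length(x) == 0L || all(x == x[1L])
    })
    if (any(mono))
        message(sum(mono), " monomorphic site(s) pruned before LD scan")
    alive <- !mono
    wbp <- windowKb * 1000
    for (cc in unique(chrom)) {
        cidx <- which(chrom == cc)
        i <- 1L
        repeat {
            rem <- cidx[alive[cidx]]
            if (i > length(rem)) break
            first <- rem[i]
            w <- rem[seq.int(i, length(rem))]
            w <- w[pos[w] - pos[first] <= wbp]
            if (length(w) >= 2L) {
                r2 <- r2Matrix(d[w, , drop = FALSE])
                diag(r2) <- 0
                inW <- rep(TRUE, length(w))
                repeat {
                    r2w <- r2
                    r2w[!inW, ] <- 0; r2w[, !inW] <- 0
                    r2w[lower.tri(r2w, diag = TRUE)] <- 0
                    hit <- which(r2w > r2Thresh, arr.ind = TRUE)
                    if (!nrow(hit)) break
                    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
                    a <- hit[1L, 1L]; b <- hit[1L, 2L]
                    sa <- w[a]; sb <- w[b]
                    drop <- if (maf[sa] < maf[sb]) a
                            else if (maf[sb] < maf[sa]) b
                            else if (pos[sa] > pos[sb]) a else b
                    inW[drop] <- FALSE
                    alive[w[drop]] <- FALSE
                }
            }
            i <- i + stepSnps
        }
    }
    kept <- ids[alive]
    pruned <- ids[!alive]
    methods::new("PruneResult", kept = kept, pruned = pruned,
        params = list(windowKb = windowKb, stepSnps = stepSnps,
                      r2Thresh = r2Thresh),
        fractionPruned = length(pruned) / length(ids))
}

#' Apply a PruneResult to a panel
#'
#' @param g the \linkS4class{GenotypePanel} the pruning was computed on.
#' @param pr a \linkS4class{PruneResult}.
#' @return The panel restricted to the kept sites.
#' @export
applyPruning <- function(g, pr) {
    subsetSites(g, which(rownames(g) %in% pr@kept))
}

#' Fraction of markers removed by pruning
#'
#' @param before,after site-id vectors (or panels) before and after pruning;
#'   \code{after} must be a subset of \code{before}.
#' @return (|before| - |after|) / |before|.
#' @export
pruningSummary <- function(before, after) {
    if (methods::is(before, "GenotypePanel")) before <- rownames(before)
    if (methods::is(after, "GenotypePanel")) after <- rownames(after)
    if (!length(before)) stop("empty site set before pruning")
    if (!all(after %in% before)) stop("'after' must be a subset of 'before'")
    (length(before) - length(after)) / length(before)
}
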