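#' Patterson-normalised genotype matrix
#'
#' Produces the sample x site matrix used for ancestry PCA: per site, missing
#' dosages are imputed with the site mean, the column is centred at its mean
#' mu, and scaled by sqrt(pHat (1 - pHat)) with pHat = mu / 2 (the binomial
#' standard deviation of one allele copy). Monomorphic sites, whose scale is
#' zero, are dropped with a reported count.
#'
#' @param g a \linkS4class{GenotypePanel} with at least 2 samples.
#' @param pseudoCount add one reference and one alternate allele to the
#'   frequency estimate before scaling (off by default).
#' @return sample x site numeric matrix (an attribute \code{"kept"} records
#'   the retained site indices).
#' @export
normalizeGenotypes <- function(g, pseudoCount = FALSE) {
    d <- dosages(g)
    if (ncol(d) < 2L) stop("need at least 2 samples")
    X <- t(d)                       # samples x sites
    nObs <- colSums(!is.na(X))
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    if (length(idx)) X[idx] <- mu[(idx - 1L) %/% nrow(X) + 1L]
    p <- if (pseudoCount) (nObs * mu + 1) / (2 * nObs + 2) else mu / 2
    scale <- sqrt(p * (1 - p))
    keep <- which(scale > 0)
    if (!length(keep)) stop("all sites monomorphic")
    nDropped <- ncol(X) - length(keep)
    if (nDropped > 0)
        message(nDropped, " monomorphic site(s) dropped before PCA")
    X <- sweep(X[, keep, drop = FALSE], 2L, mu[keep], `-`)
    X <- sweep(X, 2L, scale[keep], `/`)
    attr(X, "kept") <- keep
    X
}

#' Principal components analysis of a genotype panel
#'
#' Eigendecomposition of the sample x sample covariance of the
#' Patterson-normalised genotype matrix (divided by the number of sites
#' used). Eigenvalues are returned in descending order (all of them, so
#' their sum equals the covariance trace); the first \code{nComponents}
#' eigenvectors are returned with unit norm and the sign convention that
#' each vector's largest-magnitude entry is positive.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param nComponents eigenvectors to keep (clamped to samples - 1).
#' @param pseudoCount passed to \code{\link{normalizeGenotypes}}.
#' @return A \linkS4class{PCAResult}.
#' @export
runPCA <- function(g, nComponents = 10L, pseudoCount = FALSE) {
    X <- normalizeGenotypes(g, pseudoCount = pseudoCount)
    m <- ncol(X)
    C <- tcrossprod(X) / m
    ev <- eigen(C, symmetric = TRUE)
    k <- min(nComponents, nrow(X) - 1L, m)
    vec <- ev$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(vec[, j]))
        if (vec[i, j] < 0) vec[, j] <- -vec[, j]
    }
    rownames(vec) <- rownames(X)
    colnames(vec) <- paste0("PC", seq_len(k))
    methods::new("PCAResult", eigenvalues = ev$values,
        eigenvectors = vec, removedOutliers = list(),
        nSitesUsed = as.integer(m))
}

#' PCA with iterative sigma-threshold outlier removal
#'
#' Repeats: run PCA; flag samples whose score on any of the top \code{topk}
#' components deviates from that component's mean by more than \code{sigma}
#' standard deviations; remove them; stop when no sample is flagged or after
#' \code{maxIter} iterations. The returned result carries the removal
#' history (one character vector of sample ids per iteration that removed
#' anything).
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param sigma outlier threshold in SD (default 6).
#' @param topk components scanned for outliers (default 10).
#' @param maxIter maximum removal iterations (default 5).
#' @param nComponents eigenvectors kept in the final result.
#' @return A \linkS4class{PCAResult} for the retained samples.
#' @export
removeOutliers <- function(g, sigma = 6.0, topk = 10L, maxIter = 5L,
                           nComponents = 10L) {
    stopifnot(sigma > 0)
    history <- list()
    cur <- g
    for (it in seq_len(maxIter)) {
        res <- runPCA(cur, nComponents = max(nComponents, topk))
        vec <- res@eigenvectors
        kk <- min(topk, ncol(vec))
        out <- rep(FALSE, nrow(vec))
        for (j in seq_len(kk)) {
            s <- vec[, j]
            out <- out | abs(s - mean(s)) > sigma * sd(s)
        }
        if (!any(out)) {
            res@removedOutliers <- history
            return(res)
        }
        history[[length(history) + 1L]] <- rownames(vec)[out]
        keep <- which(!out)
        if (!length(keep)) stop("outlier removal removed every sample")
        cur <- cur[, keep]
    }
    res <- runPCA(cur, nComponents = nComponents)
    res@removedOutliers <- history
    res
}
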