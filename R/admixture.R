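EPS_F <- 1e-6

# log-likelihood of the admixture model at (Q, F); G is N x M with NA
admixtureLoglik <- function(G, Q, F) {
    P <- Q %*% F
    P[P < EPS_F] <- EPS_F; P[P > 1 - EPS_F] <- 1 - EPS_F
    ll <- G * log(P) + (2 - G) * log(1 - P)
    sum(ll, na.rm = TRUE)
}

#' Maximum-likelihood admixture fit for one K
#'
#' Estimates per-sample ancestry fractions Q (N x K, rows summing to 1) and
#' per-component allele frequencies F (K x M) by maximising
#' \deqn{\ell(Q,F) = \sum_{ij\ observed} g_{ij}\ln(\sum_k q_{ik} f_{kj}) +
#' (2 - g_{ij})\ln(\sum_k q_{ik}(1 - f_{kj}))}
#' with alternating EM updates from a seeded random start (Dirichlet rows for
#' Q, uniform F). Missing genotypes are skipped in the likelihood. The
#' log-likelihood is non-decreasing across iterations; iteration stops when
#' the increment falls below \code{tol} or after \code{maxIter} iterations.
#' F is clamped to [1e-6, 1 - 1e-6] to keep the likelihood finite. K = 1 has
#' the closed-form solution Q = 1, F = mean dosage / 2 and is returned
#' directly.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param K number of ancestral components (1 <= K <= samples).
#' @param seed seed for the random initialisation.
#' @param tol log-likelihood convergence increment (default 1e-4).
#' @param maxIter EM iteration cap (default 2000).
#' @return An \linkS4class{AdmixtureFit}.
#' @export
admixtureFit <- function(g, K, seed = 1L, tol = 1e-4, maxIter = 2000L) {
    G <- t(dosages(g))              # samples x sites
    N <- nrow(G); M <- ncol(G)
    if (K > N) stop("K cannot exceed the number of samples")
    stopifnot(K >= 1L)
    if (K == 1L) {
        Fhat <- matrix(pmin(pmax(colMeans(G, na.rm = TRUE) / 2, EPS_F),
                            1 - EPS_F), nrow = 1L)
        Q <- matrix(1, N, 1L, dimnames = list(rownames(G), NULL))
        ll1 <- admixtureLoglik(G, Q, Fhat)
        return(methods::new("AdmixtureFit", Q = Q, F = Fhat,
            loglik = ll1, K = 1L, nIter = 0L,
            converged = TRUE, seed = as.integer(seed), loglikTrace = ll1))
    }
    set.seed(seed)
    Q <- matrix(rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    F <- matrix(runif(K * M, 0.05, 0.95), K, M)
    obs <- !is.na(G)
    G0 <- G; G0[!obs] <- 0
    G2 <- 2 - G; G2[!obs] <- 0
    nObsRow <- rowSums(obs)
    ll <- -Inf; converged <- FALSE; it <- 0L
    trace <- numeric(0)
    while (it < maxIter) {
        it <- it + 1L
        P <- Q %*% F
        P[P < EPS_F] <- EPS_F; P[P > 1 - EPS_F] <- 1 - EPS_F
        U <- G0 / P              # g / p, zero where missing
        V <- G2 / (1 - P)        # (2 - g) / (1 - p)
        # F update: expected alt / (alt + ref) allele counts per component
        T1 <- crossprod(U, Q)    # M x K
        T2 <- crossprod(V, Q)
        Fnum <- t(F) * T1
        Fnew <- t(Fnum / (Fnum + t(1 - F) * T2))
        # Q update: expected ancestry of the 2*nObs allele copies
        Salt <- Q * (U %*% t(F))
        Sref <- Q * (V %*% t(1 - F))
        Qnew <- (Salt + Sref) / (2 * nObsRow)
        Qnew <- Qnew / rowSums(Qnew)
        F <- Fnew
        F[F < EPS_F] <- EPS_F; F[F > 1 - EPS_F] <- 1 - EPS_F
        Q <- Qnew
        llNew <- admixtureLoglik(G, Q, F)
        trace <- c(trace, llNew)
        if (is.finite(ll) && llNew - ll < tol) {
            ll <- llNew; converged <- TRUE; break
        }
        ll <- llNew
    }
    rownames(Q) <- rownames(G)
    methods::new("AdmixtureFit", Q = Q, F = F, loglik = ll, K = as.integer(K),
        nIter = it, converged = converged, seed = as.integer(seed),
        loglikTrace = trace)
}

#' Best-of-restarts admixture fit
#'
#' Runs \code{\link{admixtureFit}} from \code{restarts} independent seeded
#' initialisations and returns the fit with the highest log-likelihood.
#'
#' @inheritParams admixtureFit
#' @param restarts independent EM starts (default 20).
#' @return An \linkS4class{AdmixtureFit}.
#' @export
admixtureFitBest <- function(g, K, restarts = 20L, seed = 1L, tol = 1e-4,
                             maxIter = 2000L) {
    best <- NULL
    for (r in seq_len(restarts)) {
        fit <- admixtureFit(g, K, seed = childSeed(seed, paste0("r", r)),
                            tol = tol, maxIter = maxIter)
        if (is.null(best) || fit@loglik > best@loglik) best <- fit
    }
    best
}

#' Masked-entry cross-validation over a range of K
#'
#' The observed genotype entries (sample, site cells) are partitioned into
#' \code{folds} folds. For each fold and each K the fold is masked, the model
#' fitted with \code{restarts} seeded starts (best log-likelihood kept), and
#' the fold error computed as the mean squared difference between the masked
#' observed dosages and their model prediction 2 * Q F. The per-K error is
#' the mean over folds; the relative curve divides by the error of the
#' worst-fitting (highest-error) K, so comparisons across panels do not
#' depend on the absolute error scale. A partition that leaves some sample
#' or site with no observed training entry is re-randomised (up to 10
#' attempts).
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param Krange candidate K values (default 3:10).
#' @param folds cross-validation folds (default 5).
#' @param restarts EM starts per fit (default 20).
#' @param seed root seed for partitioning and fits.
#' @param tol,maxIter passed to \code{\link{admixtureFit}}.
#' @return A \linkS4class{CVCurve}.
#' @export
crossValidation <- function(g, Krange = 3:10, folds = 5L, restarts = 20L,
                            seed = 1L, tol = 1e-4, maxIter = 2000L) {
    stopifnot(folds >= 2L)
    d <- dosages(g)
    G <- t(d)
    obsIdx <- which(!is.na(G))
    set.seed(childSeed(seed, "cvfolds"))
    assign <- NULL
    for (attempt in 1:10) {
        cand <- sample(rep(seq_len(folds), length.out = length(obsIdx)))
        ok <- TRUE
        for (f in seq_len(folds)) {
            Gm <- G
            Gm[obsIdx[cand == f]] <- NA
            if (any(rowSums(!is.na(Gm)) == 0) ||
                any(colSums(!is.na(Gm)) == 0)) { ok <- FALSE; break }
        }
        if (ok) { assign <- cand; break }
    }
    if (is.null(assign))
        stop("could not find a fold partition leaving every sample and ",
             "site observed")
    foldErr <- matrix(NA_real_, length(Krange), folds,
                      dimnames = list(paste0("K", Krange), NULL))
    for (f in seq_len(folds)) {
        mask <- obsIdx[assign == f]
        Gtrain <- G
        Gtrain[mask] <- NA
        gTrain <- g
        SummarizedExperiment::assay(gTrain, "dosage") <- t(Gtrain)
        for (ki in seq_along(Krange)) {
            fit <- admixtureFitBest(gTrain, Krange[ki], restarts = restarts,
                seed = childSeed(seed, paste0("cv", f, "k", Krange[ki])),
                tol = tol, maxIter = maxIter)
            pred <- 2 * (fit@Q %*% fit@F)
            foldErr[ki, f] <- mean((G[mask] - pred[mask])^2)
        }
    }
    meanErr <- rowMeans(foldErr)
    bestK <- bestModelK(Krange, meanErr)
    methods::new("CVCurve", K = as.integer(Krange),
        meanError = unname(meanErr), foldErrors = foldErr,
        bestK = bestK, relativeError = unname(meanErr / max(meanErr)))
}

bestModelK <- function(K, err) {
    best <- K[which.min(err)]       # which.min takes the first = smaller K
    if (best == K[length(K)] && length(K) > 1L &&
        all(diff(err) < 0))
        warning("boundary minimum: CV error still decreasing at the ",
                "largest K tested")
    as.integer(best)
}

#' Best-supported number of components from a CV curve
#'
#' @param curve a \linkS4class{CVCurve}.
#' @return the K minimising the mean CV error (ties: the smaller K). A
#'   warning is raised when the minimum sits at the upper boundary of a
#'   monotone-decreasing curve.
#' @export
bestModel <- function(curve) {
    bestModelK(curve@K, curve@meanError)
}

#' Match estimated admixture components to a reference
#'
#' Components are label-switching invariant; this finds the column
#' permutation of \code{Q} minimising the total variation distance to
#' \code{Qref} and returns the aligned Q (used for parameter-recovery
#' evaluation).
#'
#' @param Q,Qref sample x K ancestry matrices with identical shape.
#' @return Q with columns permuted to best match Qref.
#' @export
alignComponents <- function(Q, Qref) {
    K <- ncol(Q)
    stopifnot(ncol(Qref) == K)
    perms <- allPermutations(K)
    best <- NULL; bestD <- Inf
    for (p in perms) {
        dist <- sum(abs(Q[, p, drop = FALSE] - Qref)) / 2
        if (dist < bestD) { bestD <- dist; best <- p }
    }
    Q[, best, drop = FALSE]
}

allPermutations <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (i in seq_len(n)) {
        sub <- allPermutations(n - 1L)
        rest <- setdiff(seq_len(n), i)
        out <- c(out, lapply(sub, function(p) c(i, rest[p])))
    }
    out
}
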