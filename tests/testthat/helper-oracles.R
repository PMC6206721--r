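# Independent brute-force oracles, shared across test files. These are
# deliberately naive translations of the documented procedures (full
# recomputation at every step, explicit loops) and never call the package
# code paths they are used to check.

# Weighted delete-one-block jackknife, written out long-hand.
bruteJackknife <- function(v, w, blocks) {
    est <- sum(v * w) / sum(w)
    ub <- unique(blocks); B <- length(ub)
    thetaMinus <- numeric(B); mB <- numeric(B)
    for (i in seq_len(B)) {
        keep <- blocks != ub[i]
        thetaMinus[i] <- sum(v[keep] * w[keep]) / sum(w[keep])
        mB[i] <- sum(w[blocks == ub[i]])
    }
    n <- sum(w); h <- n / mB
    tau <- h * est - (h - 1) * thetaMinus
    thetaJ <- B * est - sum((1 - mB / n) * thetaMinus)
    list(estimate = est,
         se = sqrt(sum((tau - thetaJ)^2 / (h - 1)) / B))
}

# Windowed greedy pruning, naive version: full r2 recomputation at every
# step, explicit window construction over the remaining-SNP order.
brutePrune <- function(d, chrom, pos, windowKb, stepSnps, r2Thresh) {
    m <- nrow(d)
    p <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    alive <- rep(TRUE, m)
    for (s in seq_len(m)) {
        x <- d[s, ]; x <- x[!is.na(x)]
        if (length(x) == 0 || all(x == x[1])) alive[s] <- FALSE
    }
    r2of <- function(i, j) {
        ok <- !is.na(d[i, ]) & !is.na(d[j, ])
        if (sum(ok) < 2) return(0)
        if (sd(d[i, ok]) == 0 || sd(d[j, ok]) == 0) return(0)
        cor(d[i, ok], d[j, ok])^2
    }
    for (cc in unique(chrom)) {
        cidx <- which(chrom == cc)
        i <- 1
        repeat {
            rem <- cidx[alive[cidx]]
            if (i > length(rem)) break
            w <- rem[i:length(rem)]
            w <- w[pos[w] - pos[rem[i]] <= windowKb * 1000]
            repeat {
                found <- FALSE
                live <- w[alive[w]]
                if (length(live) >= 2) {
                    for (ai in seq_len(length(live) - 1)) {
                        for (bi in (ai + 1):length(live)) {
                            sa <- live[ai]; sb <- live[bi]
                            if (r2of(sa, sb) > r2Thresh) {
                                drop <- if (maf[sa] < maf[sb]) sa
                                        else if (maf[sb] < maf[sa]) sb
                                        else if (pos[sa] > pos[sb]) sa
                                        else sb
                                alive[drop] <- FALSE
                                found <- TRUE
                                break
                            }
                        }
                        if (found) break
                    }
                }
                if (!found) break
            }
            i <- i + stepSnps
        }
    }
    alive
}
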