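# Shared fixtures, all built in code.

# A tiny hand-made panel: 4 sites on two chromosomes, 4 samples in 2 pops.
tinyPanel <- function() {
    d <- matrix(c(0L, 1L, 2L, 0L,
                  1L, 1L, 0L, 2L,
                  2L, 0L, 1L, 1L,
                  0L, NA, 2L, 1L), nrow = 4, byrow = TRUE)
    GenotypePanel(d, chrom = c("1", "1", "2", "2"),
                  pos = c(100L, 200L, 50L, 150L),
                  samples = paste0("S", 1:4),
                  population = c("A", "A", "B", "B"))
}

# Panel from an explicit frequency matrix: pops x sites, n diploids per pop.
panelFromFreq <- function(popFreq, n, seed = 1L, chrom = NULL, pos = NULL) {
    set.seed(seed)
    m <- ncol(popFreq)
    cols <- lapply(rownames(popFreq), function(p)
        matrix(rbinom(m * n, 2L, rep(popFreq[p, ], n)), nrow = m))
    d <- do.call(cbind, cols)
    samples <- unlist(lapply(rownames(popFreq),
                             function(p) paste0(p, "_", seq_len(n))))
    colnames(d) <- samples
    if (is.null(chrom)) chrom <- "1"
    if (is.null(pos)) pos <- seq_len(m) * 1000L
    GenotypePanel(d, chrom = chrom, pos = pos, samples = samples,
                  population = rep(rownames(popFreq), each = n))
}

# Frequency table built directly (pops x sites), fixed allele counts.
freqTable <- function(freq, nAlleles, chrom = NULL, pos = NULL) {
    if (length(nAlleles) == 1L)
        nAlleles <- matrix(nAlleles, nrow(freq), ncol(freq),
                           dimnames = dimnames(freq))
    m <- ncol(freq)
    if (is.null(chrom)) chrom <- rep("1", m)
    if (is.null(pos)) pos <- seq_len(m) * 1000L
    new("AlleleFrequencyTable", freq = freq, nAlleles = nAlleles,
        chrom = chrom, pos = as.integer(pos))
}

# Two-super-population config used by several statistical tests.
twoSuperConfig <- function(nPerPop = 30L, mSnps = 5000L, seed = 1L,
                           Fsuper = 0.08, Fpop = 0.01, ...) {
    simConfig(tree = list(
        SP1 = list(F = Fsuper, pops = c(A = Fpop, B = Fpop)),
        SP2 = list(F = Fsuper, pops = c(C = Fpop, D = Fpop))),
        nPerPop = nPerPop, mSnps = mSnps, seed = seed, ...)
}
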