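---
title: "Measuring SNP-panel ascertainment bias with panelbias"
author: "panelbias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring SNP-panel ascertainment bias with panelbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelbias)
```

## The problem

Most population-genetic analyses start from a marker panel somebody else
chose: a genotyping array's manifest, an exome capture kit's targets, or a
dispersed whole-genome sampling. Arrays in particular were designed around
ancestry-informative markers (AIMs) — SNPs with large allele-frequency
differences between reference populations. Statistics computed on such a
panel inherit that design choice: between-group distances are inflated,
leading PCA eigenvalues grow, triad-wise f3 values are distorted for
population combinations the AIMs were targeted at, and model-selection
criteria for admixture models shift. `panelbias` provides the simulation
machinery to produce genotype data where the truth is known, the panel
constructions that emulate the three ascertainment strategies, and the
statistics on which the distortion is measured.

## The simulation model

### Drift: Balding–Nichols branches

Populations are arranged in a two-level tree (super-populations containing
populations). Ancestral alternate-allele frequencies are uniform on a
configurable range; the default floor of 0.05 keeps most sites polymorphic
while still allowing monomorphic leaf sites through drift, which all
downstream code must (and does) tolerate. Every branch carries a drift
parameter F in (0, 1) and transforms the parent frequency p into a draw
from Beta(p(1−F)/F, (1−p)(1−F)/F). This distribution has mean p and
variance p(1−p)F, so F is interpretable directly as the expected
F<sub>ST</sub>-scale divergence the branch adds, and F → 0 recovers the
parent frequency exactly. Frequencies that hit 0 or 1 stay fixed, as they
would under pure drift.

The default study design (`paperlikeConfig()`) uses 5 super-populations ×
3 populations, F = 0.08 between super-populations and F = 0.01 within,
30 individuals per population and 20,000 SNPs, plus one admixed group with
70/30 ancestry from two different super-populations. These magnitudes give
between-super-population F<sub>ST</sub> around 0.09 and within around
0.01–0.02, the continental/within-continental ordering familiar from
human population panels, and the whole design simulates in seconds.

### Genotypes, admixture, missingness

Unadmixed diploid genotypes are Binomial(2, p<sub>pop</sub>) dosages.
Admixture acts at the allele-copy level: each of the two copies picks
source k with probability equal to its mixing proportion and then samples
that source's frequency. Because the copy-level choices are independent,
the dosage is marginally Binomial(2, Σ<sub>k</sub> prop<sub>k</sub>
p<sub>k</sub>), which is how it is implemented. An optional uniform
missingness rate (default 0) exercises the missing-data paths.

### LD blocks and coordinate layouts

Real panels contain runs of markers in high LD; exome panels additionally
pack their sites into gene-dense islands. `injectLDBlocks()` copies the
first genotype column of each consecutive block over the rest of the
block, then resamples every copied entry with probability `noise` from the
individual's population frequency at that site — `noise = 0` gives
complete LD, `noise = 1` restores the original distribution.
`assignCoordinates()` places sites either uniformly along synthetic
chromosomes or in clusters (`clusterSpan` bp of sites separated by `gapBp`
deserts). The simulator does not attempt coalescent-exact LD or
recombination maps; blocks are a deliberately stylised overlay, sufficient
to exercise pruning and the eigenstructure distortions complete-LD blocks
cause, but not a model of real haplotype structure.

### Ascertainment

`ascertainAims()` emulates array design: a `fractionAims` share of the
requested sites is drawn from the top decile of a differentiation ranking,
the remainder uniformly from the other sites. Two rankings are available —
across-population variance of allele frequency (`maf_variance_top`) and
|Δp| for one named population pair (`delta_pair`). The AIM share of a real
array is not documented for our reference arrays, so `fractionAims` is a
free parameter (default 0.8) rather than an estimate. With
`fractionAims = 0` the function reduces to a uniform random draw through
the same generator path, which is what the package uses as the matched
control panel.

A point worth recording: global MAF-variance ascertainment inflates f3
values near-uniformly across population triads, and Pearson correlation is
invariant to uniform scaling — so that mode alone does not reproduce the
drop in triad-f3 correlation observed for array panels. The documented
mechanism for that drop is uneven representation: markers targeted at
*specific* population contrasts. The bias-reproduction suite therefore
builds its array-like panel with `delta_pair` ascertainment on one
between-super-population pair, which distorts exactly the triads involving
those populations.

## Panel construction and QC

`genomeSchemeRegions()` reproduces the dispersed whole-genome coordinate
scheme: exclude `telomereExcl` (default 5 Mb) at each chromosome end, tile
the remainder into full `stretch` (10 kb) stretches discarding the trailing
partial stretch, and take the first `take` (258) bp of each. On the
embedded GRCh37 autosome lengths this yields a cumulative 68.7 Mb,
comparable to a high-quality exome target; the trailing-stretch and
strict-threshold readings are fixed by that cumulative-size anchor.
Region QC (`qualifyRegions`) keeps regions with minimum cohort coverage
strictly above 10× and no MAPQ0 (multi-mappable) reads, dropping sex
chromosomes by default. Variant QC keeps sites where **both** alleles have
at least 10 carriers — the reference-side condition removes near-fixed
alternate sites that typically indicate reference-sequence errors — and
removes sites with site-inbreeding coefficient F = 1 − obsHet/expHet below
−0.5, the signature of technical heterozygote excess. The inbreeding
coefficient is recomputed from genotypes with expected heterozygosity
2p̂(1−p̂); the sign convention (excess heterozygosity → negative) matches
the variant-caller annotation it replaces. Array-like site selection
matches by (chromosome, position) only, since manifests may report
strand-flipped alleles.

## LD pruning

`indepPairwise()` prunes greedily within sliding windows: a window is the
maximal run of unpruned SNPs within `windowKb` of the window's first SNP
(physical distance), the window start advances by `stepSnps` in the
remaining-SNP order (the protocol's mixed units), and within a window any
pair with dosage r² above the threshold loses one member. The removal rule
— drop the lower-MAF member, ties drop the later position — is the
package's own deterministic choice; reference pruning tools do not
document theirs, so equivalence is defined against this rule (and verified
against an independently coded brute-force version), not bit-for-bit
against any external tool. r² is the squared Pearson correlation of
dosages over pairwise-complete entries (composite LD); the data model
discards phase, so haplotype-EM r² is out of scope. Monomorphic sites are
pruned up front with a reported count. Constant vectors define r² = 0.

## F-statistics and the block jackknife

Allele frequencies are simple per-population counts; p is undefined
(`NA`) below 2 observed alleles, and every statistic skips unusable sites
per statistic rather than globally. Hudson's F<sub>ST</sub> combines
per-site numerators and denominators as a ratio of averages and is never
clamped, so small negative estimates are visible rather than hidden. The
f3 target correction c(1−c)/(n<sub>C</sub>−1) makes E[f3] = 0 under a star
phylogeny with finite samples; f4 needs no correction. f3 is reported
unnormalised by default (the sign and relative magnitude are what gets
interpreted); heterozygosity normalisation is available behind a flag.

Standard errors come from a weighted delete-one-block jackknife over
contiguous 5 Mb coordinate blocks (falling back to up to 100 equal-count
blocks when the coordinates cannot support 5 blocks). The 5 Mb default is
standard jackknife practice for human-scale LD; the original block choice
behind published Z scores is rarely documented, which is why it is a
parameter here. Ratio estimators jackknife the ratio itself (values N/D
weighted by D). A zero jackknife SE reports Z = ±Inf rather than NaN.

## PCA

`normalizeGenotypes()` mean-imputes missing entries (unbiased under
missing-at-random), centres each site and scales by √(p̂(1−p̂)) with
p̂ = μ/2 — the plain binomial normalisation, without pseudo-count; the
pseudo-count variant is available behind a flag since reference
implementations differ and neither choice is documented for the runs being
emulated. Monomorphic sites are dropped with a count.
The eigendecomposition is of the sample × sample covariance divided by the
number of sites; all eigenvalues are returned (their sum equals the
covariance trace, a conservation law the tests check), eigenvectors are
unit-norm with the largest-magnitude entry made positive so results are
reproducible across LAPACK sign choices. Outlier removal iterates: flag
samples more than `sigma` (default 6) SDs from a component mean on any of
the top `topk` components, remove, recompute, up to `maxIter` (default 5 —
the threshold is standard, the iteration cap is this package's choice).

## Admixture

The likelihood is the standard binomial admixture model
ℓ(Q, F) = Σ g log(QF) + (2−g) log(1−QF) over observed entries. It is
maximised by plain EM with simultaneous Q/F updates from a seeded random
start (Dirichlet rows for Q, uniform F). Plain EM rather than quasi-Newton
acceleration is a deliberate trade: at desk scale the extra iterations are
cheap and the monotonicity of the likelihood (asserted in the tests) gives
a simple correctness argument. F is clamped to [10⁻⁶, 1−10⁻⁶] to keep the
likelihood finite; K = 1 is returned in closed form. Restarts
(`admixtureFitBest`, default 20 seeded runs keeping the best likelihood)
mirror common practice with randomized-seed replicates.

Cross-validation masks genotype *entries* (sample–site cells), refits on
the rest, and scores the mean squared difference between masked dosages
and the model prediction 2·QF. No standard definition of the CV error
formula exists across implementations, and absolute CV errors are not
comparable across panels; the relative curve — each K's error divided by
the worst (highest-error) K's — is the package's contract, with best K the
argmin (ties to the smaller K, boundary minima flagged). The default K
range is 3–10; any range can be requested. A masking partition that would
leave a sample or site with no training data is re-randomised (up to 10
attempts).

## The ascertainment diagnostic and panel comparison

`mafVariance()` computes, per site, the variance across populations of the
frequency of the *pooled-sample* minor allele (ties to the alternate
allele). Defining the minor allele on the pooled sample rather than per
population keeps the quantity a variance of one allele's frequency;
per-population folding would conflate allele switching with
differentiation. The sample variance (denominator n<sub>pops</sub>−1) is
the default and is recorded in the report metadata, with the population
variance available behind a flag, since the choice is material at small
population counts. `comparePanels()` collects, against a designated
reference panel, the elementwise F<sub>ST</sub> difference matrices, the
Pearson correlation of matched triad-f3 vectors, leading-eigenvalue
ratios, and relative CV curves; `reportComparison()` writes deterministic
TSV tables, run metadata (seeds, parameters, conventions) and illustrative
plots — every asserted comparison runs on the numbers, never on the plots.

## What the tests do and do not show

The acceptance suite asserts, over 20 simulation seeds at a 95% frequency,
that an AIM-ascertained panel versus a size-matched random panel shows:
(a) higher between-super-population F<sub>ST</sub>, (b) a larger leading
eigenvalue, (c) lower triad-f3 correlation with the full-site reference,
and (d) a right-shifted MAF-variance distribution. These are directional
reproductions on synthetic data at reduced problem sizes (15 individuals
per population, 8,000 sites, 800-site panels; the directions were also
verified at 20,000/2,000 before fixing these sizes), chosen so the whole
suite runs in minutes on one CPU. They demonstrate that the package's
statistics respond to ascertainment the way the field observes on real
array data; they do not reproduce any particular study's magnitudes, which
depend on the real populations, the real array manifest, and panel sizes
two orders of magnitude larger. The triad set for (c) spans two
populations per super-population: with the deliberately symmetric default
tree, one-population-per-group triads all share the same expected f3 and a
correlation over them would be meaningless.

Parameter recovery is checked on a three-population design (branch
F = 0.1, 50 individuals per population, 2,000 unlinked SNPs, one 50/50
admixed group): the EM fit recovers the planted ancestry matrix with
best-permutation RMSE below 0.05. Exact-arithmetic anchors (the 68.7 Mb
genome scheme, F<sub>ST</sub> = 1 under fixed divergence, hand-computed
per-site estimator values) and brute-force oracle equivalence at 10⁻¹⁰
for f3/f4/F<sub>ST</sub>/jackknife/pruning complete the suite.

## Numerical and degenerate-input conventions

* Frequencies below 2 observed alleles are `NA` and skipped per statistic.
* Monomorphic-across-the-pair sites are excluded from F<sub>ST</sub>;
  monomorphic sites are dropped before PCA and pruning with counts.
* Site-inbreeding F is defined 0 for monomorphic sites.
* r² is 0 for constant vectors and for fewer than 2 complete pairs (with a
  warning).
* Jackknife needs ≥ 2 non-empty blocks; SE = 0 yields Z = ±Inf.
* All simulation stages derive independent child seeds from one root seed,
  so any stage is reproducible in isolation and the whole run from the
  root.

## Known limitations

* The simulator's LD overlay is stylised (exact-copy blocks plus noise),
  not coalescent; pruning behaviour on real haplotype structure will
  differ quantitatively.
* The admixture EM is unaccelerated; for panels beyond ~10⁵ sites ×
  10³ samples a quasi-Newton implementation would be preferable.
* Hudson's estimator is the primary F<sub>ST</sub>; the Weir–Cockerham
  variant is provided for cross-checking, and the two differ under strong
  sample-size imbalance.
* VCF support covers GT-based biallelic SNPs only — no genotype
  likelihoods, no indels, no BCF.
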