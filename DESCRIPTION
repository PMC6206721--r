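Package: panelbias
Title: Ascertainment Bias in SNP Panel Design for Population Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the choice of SNP panel (whole-genome
    style dispersed coordinates, exome-like clustered coordinates, or
    array-like pre-ascertained marker sets enriched for ancestry-informative
    markers) distorts downstream population-genetic inference. Implements a
    Balding-Nichols structured-population genotype simulator with admixture
    and linkage-disequilibrium blocks, panel construction and variant QC
    filters, windowed greedy LD pruning, Hudson F_ST, f3- and f4-statistics
    with weighted block-jackknife standard errors, Patterson-normalised PCA
    with iterative outlier removal, maximum-likelihood admixture estimation
    with masked-entry cross-validation, and the per-SNP across-population
    minor-allele-frequency variance diagnostic used to detect marker
    ascertainment bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, Genetics, Simulation, QualityControl
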