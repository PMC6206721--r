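pipelineKeys <- list(
    top = c("version", "seed", "input", "panels", "reference", "qc",
            "pruning", "statistics", "pca", "admixture", "outDir"),
    input = c("type", "vcf", "labels", "paperlike", "nPerPop", "mSnps"),
    panel = c("name", "scheme", "nSites", "fractionAims", "bed", "sites",
              "mode", "pair"),
    qc = c("minCarriers", "minInbreeding"),
    pruning = c("enabled", "windowKb", "stepSnps", "r2Thresh"),
    statistics = c("fst", "f3", "f4", "f4Quad", "blocksMb"),
    pca = c("enabled", "components", "outlierSigma", "topk"),
    admixture = c("enabled", "Krange", "folds", "restarts"))

checkKeys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
        stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
}

#' Validate a pipeline configuration
#'
#' The configuration is a versioned YAML document (or equivalent list):
#' an \code{input} section (either \code{type: simulate} with generator
#' settings, or \code{type: vcf} with paths), a list of \code{panels} (one
#' of which is the \code{reference}), QC, pruning, statistics, PCA and
#' admixture sections. Unknown keys anywhere are errors, so typos fail
#' before any computation.
#'
#' @param config list or path to a YAML file.
#' @return the validated configuration list, with defaults filled in.
#' @export
validatePipelineConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    checkKeys(config, pipelineKeys$top, "config")
    if (is.null(config$version)) stop("config needs a 'version'")
    if (is.null(config$input)) stop("config needs an 'input' section")
    checkKeys(config$input, pipelineKeys$input, "input")
    itype <- config$input$type
    if (is.null(itype) || !itype %in% c("simulate", "vcf"))
        stop("input$type must be 'simulate' or 'vcf'")
    if (is.null(config$panels) || !length(config$panels))
        stop("config needs at least one panel")
    for (p in config$panels) {
        checkKeys(p, pipelineKeys$panel, "panel")
        if (is.null(p$name)) stop("every panel needs a name")
        if (is.null(p$scheme) ||
            !p$scheme %in% c("all", "random", "aim", "bed", "sites"))
            stop("unknown panel scheme: ",
                 if (is.null(p$scheme)) "<missing>" else p$scheme)
    }
    panelNames <- vapply(config$panels, `[[`, "", "name")
    if (anyDuplicated(panelNames)) stop("panel names must be unique")
    if (is.null(config$reference)) config$reference <- panelNames[1]
    if (!config$reference %in% panelNames)
        stop("reference '", config$reference, "' is not a panel name")
    for (sec in c("qc", "pruning", "statistics", "pca", "admixture"))
        if (!is.null(config[[sec]]))
            checkKeys(config[[sec]], pipelineKeys[[sec]], sec)
    if (is.null(config$seed)) config$seed <- 1L
    config
}

stageLog <- function(stage, ...) {
    params <- paste(vapply(list(...), function(x)
        paste(format(x), collapse = ","), character(1)), collapse = " ")
    message(sprintf("[panelbias] stage=%s %s", stage, params))
}

#' Run the end-to-end panel-comparison pipeline
#'
#' Executes simulate/load -> panel construction -> QC filters -> LD pruning
#' -> statistics (F_ST, f3 scan, optional f4, PCA, MAF variance, optional
#' admixture CV) -> cross-panel comparison -> report, from one configuration.
#' One root seed makes the whole run reproducible; every stage logs its
#' parameters. On error a \code{FAILED} marker file is left in the output
#' directory and the error is re-raised.
#'
#' @param config list or YAML path (see
#'   \code{\link{validatePipelineConfig}}).
#' @param outDir output directory; overrides \code{config$outDir}.
#' @return invisibly, a list with the per-panel results, the
#'   \linkS4class{PanelComparison} and the written report files.
#' @export
runPipeline <- function(config, outDir = NULL) {
    config <- validatePipelineConfig(config)
    if (is.null(outDir)) outDir <- config$outDir
    if (is.null(outDir)) stop("no output directory given")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    tryCatch(
        runPipelineStages(config, outDir),
        error = function(e) {
            writeLines(conditionMessage(e), file.path(outDir, "FAILED"))
            stop(e)
        })
}

runPipelineStages <- function(config, outDir) {
    seed <- as.integer(config$seed)
    stageLog("input", type = config$input$type, seed = seed)
    if (config$input$type == "simulate") {
        sc <- do.call(paperlikeConfig, c(
            list(seed = seed),
            config$input[intersect(names(config$input),
                                   c("nPerPop", "mSnps"))]))
        fp <- simulateFrequencies(sc)
        base <- simulateGenotypes(fp, sc)
    } else {
        base <- readGenotypeVcf(config$input$vcf,
                                popLabels = config$input$labels)
        fp <- NULL
    }
    qc <- config$qc
    prune <- config$pruning
    stat <- config$statistics
    pcaCfg <- config$pca
    admCfg <- config$admixture
    blocksMb <- if (!is.null(stat$blocksMb)) stat$blocksMb else 5
    results <- list(); mafTabs <- list(); pcaRes <- list()
    for (p in config$panels) {
        stageLog("panel", name = p$name, scheme = p$scheme)
        g <- switch(p$scheme,
            all = base,
            random = {
                idx <- ascertainAims(fp, mode = "maf_variance_top",
                    fractionAims = 0, nSites = p$nSites,
                    seed = childSeed(seed, paste0("panel", p$name)))
                subsetSites(base, idx)
            },
            aim = {
                fa <- if (is.null(p$fractionAims)) 0.8 else p$fractionAims
                idx <- ascertainAims(fp,
                    mode = if (is.null(p$mode)) "maf_variance_top"
                           else p$mode,
                    fractionAims = fa, nSites = p$nSites, pair = p$pair,
                    seed = childSeed(seed, paste0("panel", p$name)))
                subsetSites(base, idx)
            },
            bed = intersectVariants(base, readBedRegions(p$bed)),
            sites = selectSites(base, readSiteList(p$sites)))
        if (!is.null(qc)) {
            if (!is.null(qc$minCarriers))
                g <- filterCarriers(g, qc$minCarriers)
            if (!is.null(qc$minInbreeding))
                g <- filterInbreeding(g, qc$minInbreeding)
            stageLog("qc", name = p$name, sites = nSites(g))
        }
        if (!is.null(prune) && isTRUE(prune$enabled)) {
            pr <- indepPairwise(g,
                windowKb = prune$windowKb %||% 10000,
                stepSnps = prune$stepSnps %||% 10,
                r2Thresh = prune$r2Thresh %||% 0.1)
            g <- applyPruning(g, pr)
            stageLog("prune", name = p$name,
                     fractionPruned = round(pr@fractionPruned, 4))
        }
        freqs <- alleleFrequencies(g)
        blocks <- assignBlocks(freqs, blocksMb = blocksMb)
        bundle <- list(
            fst = fstMatrix(freqs, blocks = blocks),
            f3 = f3Scan(freqs, blocks = blocks),
            eigenvalues = NULL, cv = NULL)
        if (is.null(pcaCfg) || !identical(pcaCfg$enabled, FALSE)) {
            pres <- if (!is.null(pcaCfg$outlierSigma))
                removeOutliers(g, sigma = pcaCfg$outlierSigma,
                    topk = pcaCfg$topk %||% 10L,
                    nComponents = pcaCfg$components %||% 10L)
            else runPCA(g, nComponents = pcaCfg$components %||% 10L)
            attr(pres, "populations") <- unname(populations(g))
            bundle$eigenvalues <- pres@eigenvalues
            pcaRes[[p$name]] <- pres
        }
        if (!is.null(stat$f4Quad)) {
            q <- stat$f4Quad
            bundle$f4 <- f4(freqs, q[1], q[2], q[3], q[4], blocks = blocks)
        }
        if (!is.null(admCfg) && isTRUE(admCfg$enabled)) {
            bundle$cv <- crossValidation(g,
                Krange = admCfg$Krange %||% 3:10,
                folds = admCfg$folds %||% 5L,
                restarts = admCfg$restarts %||% 20L,
                seed = childSeed(seed, paste0("cv", p$name)))
        }
        mafTabs[[p$name]] <- mafVariance(freqs)
        results[[p$name]] <- bundle
        stageLog("stats", name = p$name, sites = nSites(g))
    }
    comparison <- comparePanels(results, config$reference)
    files <- reportComparison(comparison, outDir, mafVar = mafTabs,
        pca = if (length(pcaRes)) pcaRes else NULL,
        metadata = list(seed = seed, configVersion = config$version))
    stageLog("report", files = length(files))
    invisible(list(results = results, comparison = comparison,
                   files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
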