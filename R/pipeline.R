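#' Run the full analysis pipeline
#'
#' Orchestrates the stages in the order the analysis prescribes:
#' optional per-sample median centering; sample network connectivity QC
#' (flagged outliers are dropped only when \code{dropOutliers = TRUE},
#' single pass); per-protein ANOVA--Tukey differential abundance with
#' volcano classification; co-expression network construction with
#' module detection, merging and reassignment; post-hoc mapping of
#' half-missing proteins; module--trait correlation; marker
#' (hypergeometric/Fisher) and ontology (Z-score) enrichment with BH
#' correction; optional kappa clustering of significant terms. Proteins
#' quantified in only one batch are excluded from QC, differential
#' testing and network construction throughout and enter only via the
#' eigenprotein mapping step.
#'
#' Every stage is a pure function of (inputs, config): identical inputs
#' and seed give identical results, and \code{\link{writeReports}}
#' output is byte-identical across reruns.
#'
#' @param proteome a \linkS4class{ProteomeSet}.
#' @param markers optional \linkS4class{GeneSetCollection} of cell-type
#'   marker sets (Fisher enrichment).
#' @param terms optional \linkS4class{GeneSetCollection} of ontology
#'   term sets (Z-score enrichment + kappa clustering of terms
#'   significant at the configured p threshold).
#' @param config a \code{\link{runConfig}}.
#' @param outDir if given, \code{\link{writeReports}} writes the eight
#'   standard result files there.
#' @param dropOutliers remove QC-flagged samples before analysis.
#' @return A list (the pipeline bundle): \code{qc}, \code{de},
#'   \code{deTable}, \code{modules}, \code{moduleTrait},
#'   \code{enrichment}, \code{termEnrichment}, \code{termClusters},
#'   \code{config}, \code{log} (stage-by-stage counts), and
#'   \code{manifest} when \code{outDir} is given.
#' @examples
#' sim <- simulateProteome(simConfig(nModules = 2, proteinsPerModule = 15,
#'                                   nBackground = 30, nHalfMissing = 4))
#' res <- runPipeline(sim$proteome, markers = sim$markers,
#'                    config = runConfig(minModuleSize = 10))
#' res$log
#' @export
runPipeline <- function(proteome, markers = NULL, terms = NULL,
                        config = runConfig(), outDir = NULL,
                        dropOutliers = FALSE) {
    stopifnot(is(proteome, "ProteomeSet"), inherits(config, "RunConfig"))
    log <- list(n_proteins = nrow(proteome),
                n_samples = ncol(proteome),
                n_complete = length(completeProteins(proteome)),
                n_half_missing = length(halfMissingProteins(proteome)))

    if (config$medianCenter) {
        v <- log2Abundance(proteome)
        v <- sweep(v, 2L, apply(v, 2L, stats::median, na.rm = TRUE))
        assays(proteome) <- list(log2 = v, mask = quantMask(proteome))
    }

    qc <- sampleConnectivity(proteome, thresholdSD = config$outlierSD)
    log$n_qc_outliers <- sum(qc$outlier)
    if (dropOutliers && any(qc$outlier)) {
        keep <- !colnames(proteome) %in% qc$sample_id[qc$outlier]
        proteome <- proteome[, keep]
        log$n_samples_dropped <- sum(!keep)
    }

    de <- anovaTukey(proteome)
    deTable <- classifyVolcano(de, pThreshold = config$pThreshold,
                               log2fcThreshold = config$log2fcThreshold,
                               pSource = config$volcanoP)
    log$n_de_tested <- nrow(de)
    log$n_de_skipped <- length(attr(de, "skipped"))

    modules <- buildNetwork(proteome, config)
    log$n_modules <- nModules(modules)
    log$n_unassigned <- sum(moduleLabels(modules) == 0L)
    log$n_reassigned <- nrow(modules@reassignments)
    log$n_half_missing_mapped <-
        sum(halfMissingAssignments(modules)$module != "M0")

    mt <- if (nModules(modules) > 0)
        moduleTrait(modules, sampleInfo(proteome)) else NULL

    enr <- NULL
    if (!is.null(markers) && nModules(modules) > 0)
        enr <- fisherCellType(modules, markers)
    termEnr <- NULL
    termClusters <- NULL
    if (!is.null(terms) && nModules(modules) > 0) {
        termEnr <- zscoreEnrichment(modules, terms)
        sig <- unique(termEnr$set[termEnr$z_p_approx <= config$pThreshold])
        if (length(sig) >= 2L) {
            pBest <- vapply(sig, function(s)
                min(termEnr$z_p_approx[termEnr$set == s]), 0)
            termClusters <- kappaCluster(
                geneSets(terms)[sig],
                universe = names(moduleLabels(modules)),
                p = pBest)
        }
    }

    out <- list(qc = qc, de = de, deTable = deTable, modules = modules,
                moduleTrait = mt, enrichment = enr,
                termEnrichment = termEnr, termClusters = termClusters,
                config = config, log = log)
    if (!is.null(outDir))
        out$manifest <- writeReports(out, outDir)
    out
}

#' Volcano plot of a differential-abundance contrast
#'
#' Convenience base-graphics volcano: log2 ratio against -log10 p,
#' increased proteins in red, decreased in green.
#'
#' @param deTable long table from \code{\link{classifyVolcano}}.
#' @param contrast which contrast to draw.
#' @param ... passed to \code{plot}.
#' @export
plotVolcano <- function(deTable, contrast = "KO_vs_WT_young", ...) {
    d <- deTable[deTable$contrast == contrast, ]
    col <- c(increased = "red", decreased = "forestgreen",
             not_significant = "grey60")[as.character(d$class)]
    plot(d$log2_ratio, -log10(d$tukey_p), col = col, pch = 16,
         xlab = "log2 ratio", ylab = "-log10 p", main = contrast, ...)
    invisible(d)
}

#' Module--trait heatmap values
#'
#' Reshapes the module--trait table into a module x (trait, stratum)
#' matrix of correlations for display; drawing is left to the caller
#' (e.g. \code{image} or \pkg{pheatmap}).
#'
#' @param mt table from \code{\link{moduleTrait}}.
#' @return numeric matrix of bicor values.
#' @export
moduleTraitMatrix <- function(mt) {
    key <- paste(mt$trait, mt$stratum, sep = ".")
    mods <- unique(mt$module)
    cols <- unique(key)
    out <- matrix(NA_real_, length(mods), length(cols),
                  dimnames = list(mods, cols))
    out[cbind(match(mt$module, mods), match(key, cols))] <- mt$r
    out
}
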