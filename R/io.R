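#' Read a log2 abundance matrix and its sample sheet
#'
#' The matrix is a TSV with protein ids in the first column and sample
#' ids as the header; empty cells and \code{"NA"} mark unquantified
#' measurements and become \code{FALSE} in the mask. The sample sheet is
#' a CSV with columns \code{sample_id}, \code{genotype}, \code{age_group},
#' \code{batch} and optionally \code{replicate}, and must cover every
#' sample in the header.
#'
#' @param matrixPath path to the TSV abundance matrix.
#' @param samplePath path to the CSV sample sheet.
#' @return A \linkS4class{ProteomeSet}; protein order is preserved.
#' @export
readAbundance <- function(matrixPath, samplePath) {
    tab <- utils::read.delim(matrixPath, header = TRUE, sep = "\t",
                             check.names = FALSE, na.strings = c("NA", ""),
                             colClasses = NA, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate protein id(s) in ", matrixPath, ": ",
             paste(unique(dup), collapse = ", "))
    values <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- ids
    sheet <- utils::read.csv(samplePath, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(sheet))
        stop("sample sheet needs a 'sample_id' column")
    rownames(sheet) <- sheet$sample_id
    unknown <- setdiff(colnames(values), sheet$sample_id)
    if (length(unknown))
        stop("sample id(s) in matrix header not in sample sheet: ",
             paste(unknown, collapse = ", "))
    ProteomeSet(values, sheet)
}

#' Write a ProteomeSet back to TSV + CSV
#'
#' Inverse of \code{\link{readAbundance}}: unquantified cells are written
#' as \code{NA}; values are written at full precision so that a
#' read/write round trip is the identity on values and mask.
#'
#' @param x a \linkS4class{ProteomeSet}.
#' @param matrixPath,samplePath output paths.
#' @return Invisibly, the two paths.
#' @export
writeAbundance <- function(x, matrixPath, samplePath) {
    v <- log2Abundance(x)
    out <- data.frame(protein = rownames(v),
                      format(v, digits = 17, trim = TRUE, scientific = FALSE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out[-1][is.na(v)] <- NA
    utils::write.table(out, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    si <- sampleInfo(x)
    si <- cbind(sample_id = rownames(si),
                si[setdiff(colnames(si), "sample_id")])
    utils::write.csv(si, samplePath, row.names = FALSE, quote = FALSE)
    invisible(c(matrixPath, samplePath))
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name, description, member, member, ...}. Duplicated members
#' within a line are dropped (count reported via \code{message}).
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSetCollection} preserving set order.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty GMT file: ", path)
        return(GeneSetCollection())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 0L) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1L], " has fewer than 3 fields: ", path)
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- vapply(fields, `[[`, "", 1L)
    ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), 0L))
    if (ndup > 0)
        message("readGMT: dropped ", ndup, " duplicated member(s)")
    GeneSetCollection(lapply(sets, unique))
}

#' Write gene sets in GMT format
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
writeGMT <- function(x, path, descriptions = NULL) {
    sets <- geneSets(x)
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- mapply(function(nm, d, s)
        paste(c(nm, d, s), collapse = "\t"),
        names(sets), descriptions, sets)
    writeLines(unlist(lines, use.names = FALSE), path)
    invisible(path)
}

#' Run configuration with the study's analysis settings as defaults
#'
#' Defaults reproduce the settings the analysis is built around: volcano
#' thresholds p <= 0.05 and |log2 ratio| > log2(1.25) (a minimum 25\%
#' fold change); unsigned network on Pearson correlation with soft
#' threshold power beta = 29; topological overlap with the "mean"
#' denominator; dynamic hybrid tree cut with deepSplit = 4, minimum
#' module size 25 and the PAM stage on; eigenprotein merge cut height
#' 0.07; kME reassignment threshold p < 0.05; sample-connectivity
#' outliers at |Z.k| > 3. Biweight midcorrelation (bicor) is reserved
#' for module--trait correlation and half-missing protein mapping.
#'
#' @param pThreshold significance cutoff for the volcano classes.
#' @param log2fcThreshold absolute log2 ratio cutoff.
#' @param beta soft threshold power (positive integer).
#' @param networkType \code{"unsigned"} (|r|^beta) or \code{"signed"}.
#' @param networkCor correlation for network construction,
#'   \code{"pearson"} or \code{"bicor"}.
#' @param tomDenom topological overlap denominator, \code{"mean"} or
#'   \code{"min"}.
#' @param deepSplit dendrogram split sensitivity, integer 0--4.
#' @param minModuleSize smallest module retained at detection.
#' @param mergeCutHeight eigenprotein dissimilarity below which modules
#'   merge, in (0,1).
#' @param pamStage assign leftover proteins to the nearest module.
#' @param reassignThreshold kME p-value below which a protein may switch
#'   modules (0 disables reassignment).
#' @param outlierSD QC flag threshold on standardized connectivity.
#' @param volcanoP which p-value drives the volcano class,
#'   \code{"tukey"} (pairwise, default) or \code{"anova"} (omnibus).
#' @param medianCenter median-center each sample before analysis
#'   (off by default; the matrix is taken as given).
#' @param seed integer seed for any randomized stage.
#' @return A validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(pThreshold = 0.05,
                      log2fcThreshold = log2(1.25),
                      beta = 29L,
                      networkType = c("unsigned", "signed"),
                      networkCor = c("pearson", "bicor"),
                      tomDenom = c("mean", "min"),
                      deepSplit = 4L,
                      minModuleSize = 25L,
                      mergeCutHeight = 0.07,
                      pamStage = TRUE,
                      reassignThreshold = 0.05,
                      outlierSD = 3,
                      volcanoP = c("tukey", "anova"),
                      medianCenter = FALSE,
                      seed = 1L) {
    cfg <- list(
        pThreshold = pThreshold,
        log2fcThreshold = log2fcThreshold,
        beta = as.integer(beta),
        networkType = match.arg(networkType),
        networkCor = match.arg(networkCor),
        tomDenom = match.arg(tomDenom),
        deepSplit = as.integer(deepSplit),
        minModuleSize = as.integer(minModuleSize),
        mergeCutHeight = mergeCutHeight,
        pamStage = isTRUE(pamStage),
        reassignThreshold = reassignThreshold,
        outlierSD = outlierSD,
        volcanoP = match.arg(volcanoP),
        medianCenter = isTRUE(medianCenter),
        seed = as.integer(seed))
    stopifnot(cfg$pThreshold > 0, cfg$pThreshold <= 1,
              cfg$log2fcThreshold > 0,
              cfg$beta >= 1L,
              cfg$deepSplit %in% 0:4,
              cfg$minModuleSize >= 1L,
              cfg$mergeCutHeight >= 0, cfg$mergeCutHeight < 1,
              cfg$reassignThreshold >= 0, cfg$reassignThreshold <= 1,
              cfg$outlierSD > 0)
    class(cfg) <- "RunConfig"
    cfg
}

#' Read/write a run configuration as YAML
#'
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(runConfig, vals)
}

#' @param config a \code{"RunConfig"} list.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path, precision = 15L)
    invisible(path)
}

#' Write the standard result tables for one pipeline run
#'
#' Emits a deterministic set of exactly eight files into \code{outDir}:
#' \code{de_results.tsv}, \code{module_assignments.tsv},
#' \code{eigenproteins.tsv}, \code{kme.tsv}, \code{module_trait.tsv},
#' \code{enrichment.tsv}, \code{qc_report.json} and
#' \code{run_config.json}. Identical inputs and seed give byte-identical
#' files. Empty result tables are written header-only.
#'
#' @param results a pipeline result bundle as returned by
#'   \code{\link{runPipeline}} (components may be \code{NULL}).
#' @param outDir output directory, created if needed.
#' @return Invisibly, a manifest data.frame (file, bytes).
#' @export
writeReports <- function(results, outDir) {
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    if (file.access(outDir, 2L) != 0L)
        stop("output directory not writable: ", outDir)
    tsv <- function(df, file) {
        path <- file.path(outDir, file)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        path
    }
    emptyIf <- function(x, cols) {
        if (is.null(x) || !NROW(x)) {
            df <- as.data.frame(stats::setNames(
                rep(list(character(0)), length(cols)), cols))
            return(df)
        }
        x
    }
    files <- character(0)

    de <- emptyIf(results$deTable,
                  c("protein", "contrast", "log2_ratio", "anova_F",
                    "anova_p", "anova_bh", "tukey_p", "class"))
    files <- c(files, tsv(de, "de_results.tsv"))

    mods <- results$modules
    if (!is.null(mods)) {
        lab <- moduleLabels(mods)
        own <- vapply(seq_along(lab), function(i) {
            if (lab[i] == 0L) NA_real_
            else kMETable(mods)[names(lab)[i], paste0("M", lab[i])]
        }, 0)
        asn <- data.frame(protein = names(lab),
                          module = paste0("M", lab),
                          kME_own = own,
                          assigned_via = "complete",
                          stringsAsFactors = FALSE)
        hm <- halfMissingAssignments(mods)
        if (NROW(hm)) {
            asn <- rbind(asn, data.frame(
                protein = hm$protein, module = hm$module,
                kME_own = hm$kME, assigned_via = "half_missing",
                stringsAsFactors = FALSE))
        }
        files <- c(files, tsv(asn, "module_assignments.tsv"))
        me <- eigenProteins(mods)
        files <- c(files, tsv(cbind(data.frame(module = rownames(me)),
                                    as.data.frame(me)),
                              "eigenproteins.tsv"))
        km <- kMETable(mods)
        files <- c(files, tsv(cbind(data.frame(protein = rownames(km)),
                                    as.data.frame(km)), "kme.tsv"))
    } else {
        files <- c(files, tsv(emptyIf(NULL, c("protein", "module",
                                              "kME_own", "assigned_via")),
                              "module_assignments.tsv"))
        files <- c(files, tsv(emptyIf(NULL, c("module")),
                              "eigenproteins.tsv"))
        files <- c(files, tsv(emptyIf(NULL, c("protein")), "kme.tsv"))
    }

    mt <- emptyIf(results$moduleTrait,
                  c("module", "trait", "stratum", "n", "r", "p", "stars"))
    files <- c(files, tsv(mt, "module_trait.tsv"))
    enr <- emptyIf(results$enrichment,
                   c("module", "set", "N", "R", "n", "r",
                     "fisher_p", "bh_p", "z"))
    files <- c(files, tsv(enr, "enrichment.tsv"))

    qcPath <- file.path(outDir, "qc_report.json")
    qc <- results$qc
    if (is.null(qc)) {
        jsonlite::write_json(list(), qcPath, auto_unbox = TRUE)
    } else {
        jsonlite::write_json(
            list(threshold_sd = attr(qc, "thresholdSD"),
                 samples = qc),
            qcPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    files <- c(files, qcPath)

    cfgPath <- file.path(outDir, "run_config.json")
    jsonlite::write_json(unclass(results$config), cfgPath,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, cfgPath)

    manifest <- data.frame(file = basename(files),
                           bytes = file.size(files),
                           stringsAsFactors = FALSE)
    invisible(manifest)
}
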