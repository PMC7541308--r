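#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay
#'   assayNames colData rowData assays<-
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ProteomeSet: a log2 protein abundance matrix with sample metadata
#'
#' A \code{ProteomeSet} extends
#' \linkS4class{SummarizedExperiment} and holds two
#' assays of identical dimension: \code{log2}, the log2-scale protein
#' abundances (proteins in rows, samples in columns), and \code{mask}, a
#' logical matrix marking which cells were actually quantified. Sample
#' metadata live in \code{colData} and must provide \code{genotype}
#' (\code{"WT"}/\code{"KO"}), \code{age_group} (\code{"young"}/\code{"old"})
#' and \code{batch}. Missing cells are represented only through the mask,
#' never as sentinel numbers.
#'
#' A protein is \emph{complete} when every cell is quantified, and
#' \emph{half-missing} when it is quantified in all samples of exactly one
#' batch of a two-equal-batch design (missing fraction exactly 0.5) --
#' the situation that arises when a protein is identified in one TMT
#' multiplex but not the other.
#'
#' @aliases ProteomeSet-class
#' @export
setClass("ProteomeSet", contains = "SummarizedExperiment")

.validProteomeSet <- function(object) {
    msg <- character(0)
    if (!all(c("log2", "mask") %in% assayNames(object)))
        return("assays 'log2' and 'mask' are both required")
    v <- assay(object, "log2")
    m <- assay(object, "mask")
    if (!is.logical(m))
        msg <- c(msg, "assay 'mask' must be a logical matrix")
    if (!identical(dim(v), dim(m)))
        msg <- c(msg, "assays 'log2' and 'mask' must have identical dimensions")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "protein ids (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    cd <- colData(object)
    need <- c("genotype", "age_group", "batch")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        if (!all(cd$genotype %in% c("WT", "KO")))
            msg <- c(msg, "genotype must be 'WT' or 'KO'")
        if (!all(cd$age_group %in% c("young", "old")))
            msg <- c(msg, "age_group must be 'young' or 'old'")
        if (any(is.na(cd$batch)))
            msg <- c(msg, "every sample needs a batch")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ProteomeSet", .validProteomeSet)

#' Construct a ProteomeSet
#'
#' @param values numeric matrix of log2 abundances, proteins x samples,
#'   with protein ids as rownames and sample ids as colnames. \code{NA}
#'   cells are taken as unquantified.
#' @param sampleData data.frame of sample metadata, one row per column of
#'   \code{values} (matched by rownames or by a \code{sample_id} column),
#'   with columns \code{genotype}, \code{age_group}, \code{batch} and
#'   optionally \code{replicate}.
#' @param mask logical matrix marking quantified cells; defaults to
#'   \code{!is.na(values)}.
#' @return A \linkS4class{ProteomeSet}.
#' @examples
#' v <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' sd <- data.frame(genotype = c("WT", "WT", "KO", "KO"),
#'                  age_group = "young", batch = "b1",
#'                  row.names = paste0("s", 1:4))
#' ProteomeSet(v, sd)
#' @export
ProteomeSet <- function(values, sampleData, mask = !is.na(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)))
        stop("'values' needs protein ids as rownames")
    if (is.null(colnames(values)))
        stop("'values' needs sample ids as colnames")
    if ("sample_id" %in% colnames(sampleData) &&
        !identical(rownames(sampleData), sampleData$sample_id))
        rownames(sampleData) <- sampleData$sample_id
    missing <- setdiff(colnames(values), rownames(sampleData))
    if (length(missing))
        stop("sample sheet does not cover sample(s): ",
             paste(missing, collapse = ", "))
    sampleData <- sampleData[colnames(values), , drop = FALSE]
    mask <- as.matrix(mask)
    dimnames(mask) <- dimnames(values)
    values[!mask] <- NA_real_
    se <- SummarizedExperiment(
        assays = list(log2 = values, mask = mask),
        colData = DataFrame(sampleData))
    new("ProteomeSet", se)
}

#' GeneSetCollection: named gene/protein sets with an optional universe
#'
#' A thin container for marker lists or ontology term memberships read
#' from GMT files. Members are unique within each set; ids are opaque
#' strings. An explicit background universe may be attached; members
#' outside it are dropped (with a reported count) at use time, not here.
#'
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (length(s) && is.null(names(s)))
        return("sets must be named")
    if (any(vapply(s, anyDuplicated, 0L) > 0))
        return("set members must be unique within each set")
    TRUE
})

#' @param sets named list of character vectors.
#' @param universe optional character vector of background ids.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets = list(), universe = character(0)) {
    new("GeneSetCollection", sets = sets, universe = universe)
}

#' ModuleSet: co-expression modules with eigenproteins and kME
#'
#' Result container for the network stage. Module labels are integers
#' with 0 meaning unassigned ("M0"); modules are numbered M1..Mk in
#' decreasing size. Eigenproteins are the first principal components of
#' the standardized within-module profiles (unit-norm, oriented to
#' correlate positively with the module-average profile); kME is the
#' Pearson correlation of each protein profile with each eigenprotein.
#'
#' @slot labels named integer vector, protein -> module id (0 unassigned).
#' @slot eigenproteins modules x samples matrix, rows "M1".."Mk".
#' @slot varExplained named numeric, fraction of module variance captured
#'   by the eigenprotein.
#' @slot kME proteins x modules Pearson correlation matrix.
#' @slot kMEPvalue matching two-sided Student p-values.
#' @slot mergeHistory data.frame log of eigenprotein-similarity merges.
#' @slot reassignments data.frame log of kME-based reassignments.
#' @slot halfMissing data.frame of post-hoc module assignments for
#'   proteins quantified in only one batch (reduced confidence, n = 8).
#' @slot params list of the settings the network was built with.
#' @aliases ModuleSet-class
#' @export
setClass("ModuleSet", representation(
    labels = "integer",
    eigenproteins = "matrix",
    varExplained = "numeric",
    kME = "matrix",
    kMEPvalue = "matrix",
    mergeHistory = "data.frame",
    reassignments = "data.frame",
    halfMissing = "data.frame",
    params = "list"))

setValidity("ModuleSet", function(object) {
    lab <- object@labels
    if (is.null(names(lab))) return("labels must be named by protein id")
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) && !identical(ids, seq_along(ids)))
        return("module ids must be consecutive 1..k")
    if (length(ids) && nrow(object@eigenproteins) != length(ids))
        return("one eigenprotein row per module is required")
    TRUE
})

setMethod("show", "ProteomeSet", function(object) {
    cat("ProteomeSet:", nrow(object), "proteins x", ncol(object),
        "samples\n")
    cat("  complete proteins:    ", length(completeProteins(object)), "\n")
    cat("  half-missing proteins:", length(halfMissingProteins(object)), "\n")
    cat("  batches:", paste(unique(colData(object)$batch), collapse = ", "),
        "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object@sets), "set(s)\n")
    if (length(object@sets)) {
        sz <- vapply(object@sets, length, 0L)
        cat("  sizes:", paste0(names(sz), "=", sz, collapse = ", "), "\n")
    }
    if (length(object@universe))
        cat("  explicit universe of", length(object@universe), "ids\n")
})

setMethod("show", "ModuleSet", function(object) {
    k <- nModules(object)
    cat("ModuleSet:", length(object@labels), "proteins in", k,
        "module(s)\n")
    if (k > 0) {
        sz <- moduleSizes(object)
        cat("  sizes:", paste0(names(sz), "=", sz, collapse = ", "), "\n")
    }
    cat("  unassigned (M0):", sum(object@labels == 0L), "\n")
    if (nrow(object@halfMissing))
        cat("  half-missing proteins mapped:", nrow(object@halfMissing), "\n")
})
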