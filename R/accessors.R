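#' Accessors for ProteomeSet and ModuleSet
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a \linkS4class{ProteomeSet} or \linkS4class{ModuleSet}.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{log2Abundance}: numeric matrix of log2 abundances with
#'   \code{NA} in unquantified cells.
#' @export
log2Abundance <- function(x) assay(x, "log2")

#' @rdname accessors
#' @export
quantMask <- function(x) assay(x, "mask")

#' @rdname accessors
#' @return \code{sampleInfo}: sample metadata as a plain data.frame.
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

#' @rdname accessors
#' @export
proteinIds <- function(x) rownames(x)

#' @rdname accessors
#' @return \code{completeProteins}: ids of proteins quantified in every
#'   sample.
#' @export
completeProteins <- function(x) {
    rownames(x)[rowSums(quantMask(x)) == ncol(x)]
}

#' @rdname accessors
#' @return \code{halfMissingProteins}: ids of proteins quantified in all
#'   samples of exactly one batch and in none of the other, in a
#'   two-equal-batch design (missing fraction exactly 0.5).
#' @export
halfMissingProteins <- function(x) {
    m <- quantMask(x)
    batch <- sampleInfo(x)$batch
    tab <- table(batch)
    if (length(tab) != 2L || tab[1] != tab[2]) return(character(0))
    out <- character(0)
    for (b in names(tab)) {
        inb <- batch == b
        full <- rowSums(m[, inb, drop = FALSE]) == sum(inb) &
            rowSums(m[, !inb, drop = FALSE]) == 0L
        out <- c(out, rownames(m)[full])
    }
    sort(unique(out))
}

#' @rdname accessors
#' @param complete if \code{TRUE} return only the fully quantified
#'   proteins (no \code{NA}s), the matrix every network/DE stage runs on.
#' @export
abundanceMatrix <- function(x, complete = TRUE) {
    v <- log2Abundance(x)
    if (complete) v[completeProteins(x), , drop = FALSE] else v
}

#' @rdname accessors
#' @export
moduleLabels <- function(x) x@labels

#' @rdname accessors
#' @export
eigenProteins <- function(x) x@eigenproteins

#' @rdname accessors
#' @export
varExplained <- function(x) x@varExplained

#' @rdname accessors
#' @export
kMETable <- function(x) x@kME

#' @rdname accessors
#' @export
kMEPvalue <- function(x) x@kMEPvalue

#' @rdname accessors
#' @export
nModules <- function(x) {
    k <- unique(x@labels[x@labels > 0L])
    length(k)
}

#' @rdname accessors
#' @return \code{moduleSizes}: named integer vector, "M1".."Mk" in
#'   decreasing size.
#' @export
moduleSizes <- function(x) {
    lab <- x@labels[x@labels > 0L]
    if (!length(lab)) return(integer(0))
    tab <- table(factor(lab, levels = sort(unique(lab))))
    out <- as.integer(tab)
    names(out) <- paste0("M", names(tab))
    out
}

#' @rdname accessors
#' @export
halfMissingAssignments <- function(x) x@halfMissing

#' @rdname accessors
#' @return \code{moduleMembers}: named list of protein ids per module
#'   ("M1".."Mk"), excluding M0.
#' @export
moduleMembers <- function(x) {
    lab <- x@labels
    ids <- sort(unique(lab[lab > 0L]))
    out <- lapply(ids, function(i) names(lab)[lab == i])
    names(out) <- paste0("M", ids)
    out
}

#' @rdname accessors
#' @param name set name.
#' @export
geneSets <- function(x) x@sets

#' @rdname accessors
#' @export
setUniverse <- function(x) x@universe
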