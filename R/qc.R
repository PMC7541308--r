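#' Sample network connectivity outlier detection
#'
#' The Oldham-style sample QC: over the complete proteins, compute the
#' inter-sample Pearson correlation matrix C, each sample's connectivity
#' k_i = sum_{j != i} C_ij, and the standardized connectivity
#' Z.k = (k - mean(k)) / sd(k). Samples with |Z.k| beyond
#' \code{thresholdSD} (default 3) standard deviations from the mean are
#' flagged as network outliers. Z.k is invariant under sample-wise
#' affine transforms of the abundances.
#'
#' @param x a \linkS4class{ProteomeSet} with at least 3 samples.
#' @param thresholdSD flag threshold on |Z.k|.
#' @param perBatch if \code{TRUE}, compute connectivity separately
#'   within each batch instead of on the combined matrix.
#' @return A data.frame of class \code{"QCReport"} with columns
#'   \code{sample_id}, \code{batch}, \code{k}, \code{Z_k},
#'   \code{outlier}; the threshold is attached as attribute
#'   \code{"thresholdSD"}.
#' @examples
#' sim <- simulateProteome(simConfig(nModules = 2, proteinsPerModule = 10,
#'                                   nBackground = 20, nHalfMissing = 0))
#' sampleConnectivity(sim$proteome)
#' @export
sampleConnectivity <- function(x, thresholdSD = 3, perBatch = FALSE) {
    X <- abundanceMatrix(x, complete = TRUE)
    if (ncol(X) < 3L)
        stop("sample connectivity needs at least 3 samples")
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance sample(s): ",
             paste(colnames(X)[sds == 0], collapse = ", "))
    batch <- sampleInfo(x)$batch
    one <- function(cols) {
        C <- stats::cor(X[, cols, drop = FALSE])
        k <- rowSums(C) - 1
        Z <- if (stats::sd(k) == 0) rep(0, length(k)) else
            (k - mean(k)) / stats::sd(k)
        data.frame(sample_id = colnames(X)[cols],
                   batch = batch[cols],
                   k = k, Z_k = Z,
                   outlier = abs(Z) > thresholdSD,
                   row.names = NULL, stringsAsFactors = FALSE)
    }
    rep <- if (perBatch) {
        do.call(rbind, lapply(split(seq_len(ncol(X)), batch), one))
    } else {
        one(seq_len(ncol(X)))
    }
    rownames(rep) <- NULL
    attr(rep, "thresholdSD") <- thresholdSD
    class(rep) <- c("QCReport", "data.frame")
    rep
}
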