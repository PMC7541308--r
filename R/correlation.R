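#' Biweight midcorrelation (bicor)
#'
#' Outlier-robust correlation built on Tukey biweights around the
#' median. For a vector x with median med(x) and (unscaled) median
#' absolute deviation mad(x), set u_i = (x_i - med(x)) / (9 mad(x)) and
#' weight w_i = (1 - u_i^2)^2 I(|u_i| < 1); then
#' \deqn{r = \frac{\sum_i w_{x,i}(x_i - med(x))\, w_{y,i}(y_i - med(y))}
#'   {\sqrt{\sum_i [w_{x,i}(x_i - med(x))]^2}\,
#'    \sqrt{\sum_i [w_{y,i}(y_i - med(y))]^2}}.}
#'
#' When mad(x) = 0 the biweight is undefined and that side falls back to
#' Pearson weighting (mean-centering, unit weights) with a warning --
#' the conventional robust-correlation fallback. The same unit-weight
#' treatment can be requested explicitly via \code{robustX}/\code{robustY},
#' which is how binary traits (whose mad is degenerate) are handled in
#' module--trait correlation.
#'
#' @param x numeric vector, or a matrix whose \emph{columns} are
#'   variables (samples in rows).
#' @param y optional second vector/matrix; with a matrix \code{x} and
#'   \code{y = NULL} all pairwise column correlations are returned.
#' @param robustX,robustY use biweights on the respective side
#'   (\code{FALSE} = mean-centering with unit weights, i.e. the Pearson
#'   treatment of that side).
#' @param pairwiseComplete drop incomplete pairs per correlation
#'   (requires >= 3 shared observations, else \code{NA}).
#' @return A correlation scalar or matrix in [-1, 1].
#' @examples
#' bicor(1:5, c(5, 4, 3, 2, 1))       # exactly -1
#' bicor(c(1, 2, 3, 4, 100), 1:5)     # outlier downweighted
#' @export
bicor <- function(x, y = NULL, robustX = TRUE, robustY = TRUE,
                  pairwiseComplete = FALSE) {
    if (is.matrix(x) || is.data.frame(x)) {
        x <- as.matrix(x)
        ym <- if (is.null(y)) x else as.matrix(y)
        if (!pairwiseComplete && !anyNA(x) && !anyNA(ym)) {
            tx <- .bicorWeighted(x, robustX)
            ty <- if (is.null(y)) tx else .bicorWeighted(ym, robustY)
            r <- crossprod(tx$robust, ty$robust)
            # any pair touching a zero-mad vector is Pearson on both sides
            if (any(tx$bad) || any(ty$bad)) {
                mask <- outer(tx$bad, ty$bad, "|")
                rp <- crossprod(tx$plain, ty$plain)
                r[mask] <- rp[mask]
            }
            return(pmin(pmax(r, -1), 1))
        }
        out <- matrix(NA_real_, ncol(x), ncol(ym),
                      dimnames = list(colnames(x), colnames(ym)))
        for (i in seq_len(ncol(x)))
            for (j in seq_len(ncol(ym)))
                out[i, j] <- bicor(x[, i], ym[, j], robustX, robustY,
                                   pairwiseComplete)
        return(out)
    }
    stopifnot(!is.null(y), length(x) == length(y))
    ok <- if (pairwiseComplete) !is.na(x) & !is.na(y) else
        rep(TRUE, length(x))
    if (sum(ok) < 3L) return(NA_real_)
    a <- .bicorWeighted(cbind(x[ok]), robustX)
    b <- .bicorWeighted(cbind(y[ok]), robustY)
    r <- if (a$bad || b$bad) sum(a$plain * b$plain) else
        sum(a$robust * b$robust)
    min(max(r, -1), 1)
}

# Per-column weighted, centered, unit-norm transforms; crossprod of two
# such matrices is the bicor matrix. 'plain' holds the Pearson
# (mean-centered) transform used when a pair must fall back because one
# side has mad = 0.
.bicorWeighted <- function(x, robust = TRUE) {
    rob <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
    plain <- rob
    bad <- logical(ncol(x))
    for (j in seq_len(ncol(x))) {
        v <- x[, j]
        med <- stats::median(v)
        madv <- stats::mad(v, constant = 1)
        p <- v - mean(v)
        nrmp <- sqrt(sum(p^2))
        plain[, j] <- if (nrmp > 0) p / nrmp else NA_real_
        if (robust && madv > 0) {
            u <- (v - med) / (9 * madv)
            w <- (1 - u^2)^2 * (abs(u) < 1)
            a <- w * (v - med)
            nrm <- sqrt(sum(a^2))
            rob[, j] <- if (nrm > 0) a / nrm else NA_real_
        } else {
            bad[j] <- robust && madv == 0
            rob[, j] <- plain[, j]
        }
    }
    if (any(bad))
        warning("bicor: mad = 0, Pearson fallback for: ",
                paste((colnames(x) %||% as.character(seq_len(ncol(x))))[bad],
                      collapse = ", "))
    list(robust = rob, plain = plain, bad = bad)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise protein correlation matrix
#'
#' Correlates the rows (proteins) of the complete abundance matrix,
#' by Pearson (the network-construction default) or biweight
#' midcorrelation. With \code{pairwiseComplete} each pair uses its
#' shared quantified samples (at least 3, else \code{NA}).
#'
#' @param x a \linkS4class{ProteomeSet} or a proteins x samples matrix.
#' @param method \code{"pearson"} or \code{"bicor"}.
#' @param pairwiseComplete use pairwise-complete observations.
#' @return Symmetric proteins x proteins correlation matrix with unit
#'   diagonal; the method is attached as attribute \code{"method"}.
#' @export
correlationMatrix <- function(x, method = c("pearson", "bicor"),
                              pairwiseComplete = FALSE) {
    method <- match.arg(method)
    X <- if (is(x, "ProteomeSet"))
        abundanceMatrix(x, complete = !pairwiseComplete) else as.matrix(x)
    tX <- t(X)
    r <- if (method == "pearson") {
        stats::cor(tX, use = if (pairwiseComplete)
            "pairwise.complete.obs" else "everything")
    } else {
        bicor(tX, pairwiseComplete = pairwiseComplete)
    }
    r <- (r + t(r)) / 2
    diag(r) <- 1
    attr(r, "method") <- method
    r
}
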