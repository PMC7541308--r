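.GROUPS <- c("WT.young", "KO.young", "WT.old", "KO.old")

.CONTRASTS <- list(
    KO_vs_WT_young = c("KO.young", "WT.young"),
    KO_vs_WT_old   = c("KO.old",   "WT.old"),
    old_vs_young_WT = c("WT.old",  "WT.young"),
    old_vs_young_KO = c("KO.old",  "KO.young"))

#' Per-protein one-way ANOVA with Tukey HSD post-hoc tests
#'
#' For every complete protein, a four-group one-way ANOVA across the
#' genotype-by-age cells (WT.young, KO.young, WT.old, KO.old):
#' F = MSB/MSE with (k-1, N-k) degrees of freedom, and Tukey HSD for
#' all six group pairs, q_ij = |m_i - m_j| / sqrt((MSE/2)(1/n_i + 1/n_j))
#' referred to the studentized range distribution with k groups and N-k
#' df. Log2 ratios are reported for the four displayed contrasts (KO
#' minus WT within each age, old minus young within each genotype).
#' Proteins with any unquantified cell are excluded (attribute
#' \code{"skipped"}); a protein with MSE = 0 but unequal group means is
#' reported with p = 0 and flagged \code{degenerate}. A BH-adjusted
#' ANOVA p across proteins is emitted for information only; the volcano
#' filter operates on raw p.
#'
#' @param x a \linkS4class{ProteomeSet}; each group needs >= 2 samples.
#' @return A data.frame of class \code{"DEResult"}, one row per protein:
#'   group means, \code{F}, \code{anova_p}, \code{anova_bh},
#'   \code{tukey_p_<pair>} for the six pairs, \code{ratio_<contrast>}
#'   for the four contrasts, and \code{degenerate}.
#' @export
anovaTukey <- function(x) {
    X <- abundanceMatrix(x, complete = TRUE)
    si <- sampleInfo(x)
    grp <- factor(paste(si$genotype, si$age_group, sep = "."),
                  levels = .GROUPS)
    if (any(table(grp) < 2L))
        stop("every genotype-by-age group needs at least 2 samples")
    k <- nlevels(grp)
    N <- ncol(X)
    ng <- as.integer(table(grp))
    means <- vapply(levels(grp),
                    function(g) rowMeans(X[, grp == g, drop = FALSE]),
                    numeric(nrow(X)))
    means <- matrix(means, nrow = nrow(X),
                    dimnames = list(rownames(X), levels(grp)))
    grand <- rowMeans(X)
    ssb <- as.vector((means - grand)^2 %*% ng)
    ssw <- numeric(nrow(X))
    for (g in seq_len(k)) {
        cols <- grp == levels(grp)[g]
        ssw <- ssw + rowSums((X[, cols, drop = FALSE] - means[, g])^2)
    }
    dfB <- k - 1L
    dfW <- N - k
    mse <- ssw / dfW
    Fstat <- (ssb / dfB) / mse
    degenerate <- mse == 0 & ssb > 0
    Fstat[mse == 0 & ssb == 0] <- 0
    Fstat[degenerate] <- Inf
    pAnova <- stats::pf(Fstat, dfB, dfW, lower.tail = FALSE)
    pAnova[mse == 0 & ssb == 0] <- 1

    res <- data.frame(protein = rownames(X), means,
                      F = Fstat, anova_p = pAnova,
                      anova_bh = bhAdjust(pAnova),
                      check.names = FALSE, stringsAsFactors = FALSE)
    pairs <- utils::combn(levels(grp), 2L)
    for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        na <- ng[match(a, levels(grp))]; nb <- ng[match(b, levels(grp))]
        se <- sqrt((mse / 2) * (1 / na + 1 / nb))
        q <- abs(means[, a] - means[, b]) / se
        p <- stats::ptukey(q, nmeans = k, df = dfW, lower.tail = FALSE)
        p[se == 0 & means[, a] == means[, b]] <- 1
        p[se == 0 & means[, a] != means[, b]] <- 0
        res[[paste0("tukey_p_", a, "_vs_", b)]] <- p
    }
    for (cn in names(.CONTRASTS)) {
        pr <- .CONTRASTS[[cn]]
        res[[paste0("ratio_", cn)]] <- means[, pr[1L]] - means[, pr[2L]]
    }
    res$degenerate <- degenerate
    attr(res, "skipped") <- setdiff(rownames(x), rownames(X))
    attr(res, "groups") <- stats::setNames(ng, levels(grp))
    attr(res, "df") <- c(dfB = dfB, dfW = dfW)
    class(res) <- c("DEResult", "data.frame")
    res
}

.tukeyPairFor <- function(contrast) {
    pr <- sort(match(.CONTRASTS[[contrast]], .GROUPS))
    paste0("tukey_p_", .GROUPS[pr[1L]], "_vs_", .GROUPS[pr[2L]])
}

#' Volcano classification of differential abundance
#'
#' A contrast is called \code{increased} when its p-value is at or below
#' \code{pThreshold} (boundary inclusive) and its log2 ratio exceeds
#' \code{+log2fcThreshold}; \code{decreased} symmetrically; otherwise
#' \code{not_significant}. The defaults, p <= 0.05 and
#' |log2 ratio| > log2(1.25), correspond to a minimum 25\% linear fold
#' change in either direction.
#'
#' The default method classifies bare vectors; the \code{DEResult}
#' method expands a \code{\link{anovaTukey}} table into one row per
#' protein x contrast, driven by the Tukey pairwise p for that contrast
#' (\code{pSource = "tukey"}, the default) or by the ANOVA omnibus p.
#'
#' @param x numeric vector of log2 ratios, or a \code{"DEResult"}.
#' @param p numeric vector of p-values (default method).
#' @param pThreshold,log2fcThreshold classification thresholds.
#' @param ... passed between methods.
#' @return Default method: a factor with levels \code{increased},
#'   \code{decreased}, \code{not_significant}. DEResult method: a long
#'   data.frame (protein, contrast, log2_ratio, anova_F, anova_p,
#'   anova_bh, tukey_p, class).
#' @examples
#' classifyVolcano(c(0.5, 0.2, -1), p = c(0.01, 0.001, 0.05))
#' @export
classifyVolcano <- function(x, ...) UseMethod("classifyVolcano")

#' @rdname classifyVolcano
#' @export
classifyVolcano.default <- function(x, p, pThreshold = 0.05,
                                    log2fcThreshold = log2(1.25), ...) {
    stopifnot(pThreshold > 0, log2fcThreshold > 0, length(x) == length(p))
    cls <- rep("not_significant", length(x))
    cls[p <= pThreshold & x > log2fcThreshold] <- "increased"
    cls[p <= pThreshold & x < -log2fcThreshold] <- "decreased"
    factor(cls, levels = c("increased", "decreased", "not_significant"))
}

#' @param pSource which p-value drives the class, \code{"tukey"}
#'   (pairwise, default) or \code{"anova"} (omnibus).
#' @rdname classifyVolcano
#' @export
classifyVolcano.DEResult <- function(x, pThreshold = 0.05,
                                     log2fcThreshold = log2(1.25),
                                     pSource = c("tukey", "anova"), ...) {
    pSource <- match.arg(pSource)
    out <- lapply(names(.CONTRASTS), function(cn) {
        ratio <- x[[paste0("ratio_", cn)]]
        tk <- x[[.tukeyPairFor(cn)]]
        p <- if (pSource == "tukey") tk else x$anova_p
        data.frame(protein = x$protein, contrast = cn,
                   log2_ratio = ratio, anova_F = x$F,
                   anova_p = x$anova_p, anova_bh = x$anova_bh,
                   tukey_p = tk,
                   class = classifyVolcano(ratio, p, pThreshold,
                                           log2fcThreshold),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out[order(out$protein, out$contrast), , drop = FALSE]
}
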