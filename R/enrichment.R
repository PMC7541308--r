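.STARS <- function(p) {
    out <- rep("", length(p))
    out[!is.na(p) & p < 0.05] <- "*"
    out[!is.na(p) & p < 0.01] <- "**"
    out[!is.na(p) & p < 0.001] <- "***"
    out[!is.na(p) & p < 1e-4] <- "****"
    out
}

#' Module--trait correlation
#'
#' Biweight midcorrelation between each module eigenprotein and each
#' binary trait (genotype KO = 1, age old = 1), with the robust
#' weighting disabled on the trait side (a binary vector has a
#' degenerate mad). Computed jointly over all samples and within each
#' stratum of the other factor: genotype within all/young/old samples,
#' age within all/WT/KO. P-values come from the Student transform of r;
#' significance stars mark 0.05 / 0.01 / 0.001 / 0.0001. A trait
#' constant within a stratum is emitted as \code{NA}.
#'
#' @param modules a \linkS4class{ModuleSet} or a modules x samples
#'   eigenprotein matrix.
#' @param samples sample metadata data.frame (from
#'   \code{\link{sampleInfo}}) with rownames matching the eigenprotein
#'   columns.
#' @return data.frame (module, trait, stratum, n, r, p, stars).
#' @export
moduleTrait <- function(modules, samples) {
    ME <- if (is(modules, "ModuleSet")) eigenProteins(modules) else modules
    stopifnot(all(colnames(ME) %in% rownames(samples)))
    samples <- samples[colnames(ME), , drop = FALSE]
    traits <- list(
        genotype_KO = as.numeric(samples$genotype == "KO"),
        age_old = as.numeric(samples$age_group == "old"))
    strata <- list(
        genotype_KO = list(all = rep(TRUE, nrow(samples)),
                           young = samples$age_group == "young",
                           old = samples$age_group == "old"),
        age_old = list(all = rep(TRUE, nrow(samples)),
                       WT = samples$genotype == "WT",
                       KO = samples$genotype == "KO"))
    out <- list()
    for (tr in names(traits)) {
        for (st in names(strata[[tr]])) {
            keep <- strata[[tr]][[st]]
            y <- traits[[tr]][keep]
            n <- sum(keep)
            for (m in rownames(ME)) {
                if (n < 3L || stats::var(y) == 0) {
                    r <- NA_real_; p <- NA_real_
                } else {
                    r <- bicor(ME[m, keep], y, robustY = FALSE)
                    p <- corPvalue(r, n)
                }
                out[[length(out) + 1L]] <- data.frame(
                    module = m, trait = tr, stratum = st, n = n,
                    r = r, p = p, stars = .STARS(p),
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, out)
}

# shared overlap bookkeeping for both enrichment statistics
.overlapTable <- function(modules, sets, universe) {
    if (is(modules, "ModuleSet")) modules <- moduleMembers(modules)
    if (is(sets, "GeneSetCollection")) {
        if (!length(universe) && length(setUniverse(sets)))
            universe <- setUniverse(sets)
        sets <- geneSets(sets)
    }
    if (!length(universe))
        stop("an enrichment universe is required")
    universe <- unique(universe)
    N <- length(universe)
    dropped <- sum(vapply(sets, function(s) sum(!s %in% universe), 0L))
    if (dropped > 0)
        message("enrichment: ", dropped,
                " set member(s) outside the universe dropped")
    rows <- list()
    for (mod in names(modules)) {
        n <- length(intersect(modules[[mod]], universe))
        for (st in names(sets)) {
            R <- length(intersect(sets[[st]], universe))
            if (R == 0L || n == 0L) next  # skipped, nothing testable
            r <- length(intersect(intersect(modules[[mod]], universe),
                                  sets[[st]]))
            rows[[length(rows) + 1L]] <- data.frame(
                module = mod, set = st, N = N, R = R, n = n, r = r,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' One-tailed Fisher exact (hypergeometric) cell-type enrichment
#'
#' For each (module, marker set) pair over a common background universe
#' N, with R set members and n module members in the universe and r in
#' the overlap, the enrichment p-value is the hypergeometric upper tail
#' P(X >= r). P-values are Benjamini--Hochberg corrected across all
#' module x set tests jointly (\code{family = "all"}, the default) or
#' within each set. The Z-score of \code{\link{zscoreEnrichment}} is
#' reported alongside.
#'
#' @param modules a \linkS4class{ModuleSet} or named list of module
#'   member ids.
#' @param sets a \linkS4class{GeneSetCollection} or named list of
#'   marker sets.
#' @param universe background ids; defaults to the network proteins
#'   (all labeled proteins of the ModuleSet, including M0) or an
#'   explicit universe attached to the collection.
#' @param family BH family: all tests jointly or per set.
#' @return data.frame (module, set, N, R, n, r, fisher_p, bh_p, z),
#'   one row per testable pair.
#' @export
fisherCellType <- function(modules, sets, universe = character(0),
                           family = c("all", "perSet")) {
    family <- match.arg(family)
    if (is(modules, "ModuleSet") && !length(universe))
        universe <- names(moduleLabels(modules))
    tab <- .overlapTable(modules, sets, universe)
    if (is.null(tab)) return(tab)
    tab$fisher_p <- stats::phyper(tab$r - 1, tab$R, tab$N - tab$R, tab$n,
                                  lower.tail = FALSE)
    tab$bh_p <- if (family == "all") bhAdjust(tab$fisher_p) else
        stats::ave(tab$fisher_p, tab$set, FUN = bhAdjust)
    tab$z <- .overlapZ(tab)
    tab
}

.overlapZ <- function(tab) {
    with(tab, {
        expct <- n * R / N
        vr <- n * (R / N) * (1 - R / N) * (1 - (n - 1) / (N - 1))
        ifelse(vr > 0, (r - expct) / sqrt(vr), NA_real_)
    })
}

#' Z-score over-representation of ontology terms
#'
#' The normal approximation to the hypergeometric overlap with finite
#' population correction:
#' \deqn{Z = \frac{r - nR/N}{\sqrt{n (R/N)(1 - R/N)(1 - (n-1)/(N-1))}}}
#' with a one-sided normal p = 1 - Phi(Z), Benjamini--Hochberg adjusted.
#' The p-value is an approximation to the exact tail and is labeled as
#' such in the output column name.
#'
#' @inheritParams fisherCellType
#' @return data.frame (module, set, N, R, n, r, z, z_p_approx, bh_p).
#' @export
zscoreEnrichment <- function(modules, sets, universe = character(0)) {
    if (is(modules, "ModuleSet") && !length(universe))
        universe <- names(moduleLabels(modules))
    tab <- .overlapTable(modules, sets, universe)
    if (is.null(tab)) return(tab)
    keep <- tab$R > 0 & tab$R < tab$N & tab$n > 0 & tab$n < tab$N
    if (any(!keep))
        message("zscoreEnrichment: ", sum(!keep),
                " degenerate test(s) skipped")
    tab <- tab[keep, , drop = FALSE]
    tab$z <- .overlapZ(tab)
    tab$z_p_approx <- stats::pnorm(tab$z, lower.tail = FALSE)
    tab$bh_p <- bhAdjust(tab$z_p_approx)
    tab
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false discovery rate control: q_(i) = min_{j >= i}
#' (p_(j) m / j), capped at 1, returned in the input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Cohen's kappa clustering of enriched terms
#'
#' Pairwise Cohen's kappa between the term membership indicator vectors
#' over the universe (2x2 counts a both / b, c one only / d neither:
#' po = (a+d)/N, pe = ((a+b)(a+c) + (c+d)(b+d))/N^2, kappa =
#' (po - pe)/(1 - pe)); degenerate pe = 1 gives kappa 1 for identical
#' memberships, else 0. Terms are average-linkage clustered on
#' 1 - kappa and the tree is cut so that within-cluster linkage kappa
#' stays at or above \code{kappaThreshold}; each cluster is represented
#' by its member with the smallest enrichment p (when given).
#'
#' @param sets named list (or \linkS4class{GeneSetCollection}) of term
#'   memberships; at least 2 terms.
#' @param universe background ids.
#' @param kappaThreshold linkage kappa cut (default 0.3).
#' @param p optional named enrichment p-values used to pick
#'   representatives.
#' @return List of class \code{"TermClusterSet"}: \code{kappa} matrix,
#'   \code{clusters} (named integer), \code{representatives}
#'   (data.frame cluster, term, p).
#' @export
kappaCluster <- function(sets, universe, kappaThreshold = 0.3, p = NULL) {
    if (is(sets, "GeneSetCollection")) sets <- geneSets(sets)
    stopifnot(length(sets) >= 2L)
    universe <- unique(universe)
    N <- length(universe)
    M <- vapply(sets, function(s) universe %in% s, logical(N))
    K <- matrix(1, length(sets), length(sets),
                dimnames = list(names(sets), names(sets)))
    for (i in seq_along(sets)[-1L]) {
        for (j in seq_len(i - 1L)) {
            K[i, j] <- K[j, i] <- cohenKappa(M[, i], M[, j])
        }
    }
    hc <- stats::hclust(stats::as.dist(1 - K), method = "average")
    clusters <- stats::cutree(hc, h = 1 - kappaThreshold)
    reps <- if (is.null(p)) {
        data.frame(cluster = unique(clusters),
                   term = names(clusters)[!duplicated(clusters)],
                   p = NA_real_)
    } else {
        do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
            terms <- names(clusters)[clusters == cl]
            best <- terms[which.min(p[terms])]
            data.frame(cluster = cl, term = best,
                       p = unname(p[best]))
        }))
    }
    structure(list(kappa = K, clusters = clusters,
                   representatives = reps, threshold = kappaThreshold),
              class = "TermClusterSet")
}

#' Cohen's kappa between two logical membership vectors
#'
#' @param a,b logical vectors of equal length over the same universe.
#' @return Chance-corrected agreement in [-1, 1].
#' @export
cohenKappa <- function(a, b) {
    stopifnot(length(a) == length(b))
    N <- length(a)
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    po <- (n11 + n00) / N
    pe <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / N^2
    if (pe >= 1) {
        message("cohenKappa: degenerate identical marginals")
        return(if (all(a == b)) 1 else 0)
    }
    (po - pe) / (1 - pe)
}
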