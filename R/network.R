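#' Soft-threshold adjacency
#'
#' Converts correlation to connection strength without a hard cutoff:
#' unsigned a_ij = |r_ij|^beta, signed a_ij = ((1 + r_ij)/2)^beta. The
#' diagonal is set to 0 so downstream connectivity sums exclude
#' self-connections.
#'
#' @param corr symmetric correlation matrix.
#' @param beta soft threshold power (>= 1).
#' @param networkType \code{"unsigned"} or \code{"signed"}.
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @export
adjacencyMatrix <- function(corr, beta = 29,
                            networkType = c("unsigned", "signed")) {
    networkType <- match.arg(networkType)
    stopifnot(beta >= 1)
    a <- if (networkType == "unsigned") abs(corr)^beta
         else ((1 + corr) / 2)^beta
    diag(a) <- 0
    a
}

#' Topological overlap matrix (TOM)
#'
#' Similarity combining direct connection and shared-neighbor
#' connectivity: with L_ij = sum_u A_iu A_uj and k_i = sum_u A_iu,
#' \deqn{\omega_{ij} = \frac{L_{ij} + A_{ij}}{f(k_i, k_j) + 1 - A_{ij}}}
#' where f is \code{min} (the classical denominator) or \code{mean}.
#' The diagonal is 1 by convention.
#'
#' @param A symmetric adjacency with zero diagonal, entries in [0, 1].
#' @param denom denominator variant, \code{"mean"} or \code{"min"}.
#' @return Symmetric TOM in [0, 1] with unit diagonal; \code{denom} and
#'   \code{beta} (if present on \code{A}) attached as attributes.
#' @export
tomSimilarity <- function(A, denom = c("mean", "min")) {
    denom <- match.arg(denom)
    if (any(A < 0 | A > 1))
        stop("adjacency entries must lie in [0, 1]")
    if (max(abs(A - t(A))) > 1e-12)
        stop("adjacency must be symmetric")
    diag(A) <- 0
    L <- A %*% A
    k <- rowSums(A)
    f <- if (denom == "min") outer(k, k, pmin) else outer(k, k, "+") / 2
    w <- (L + A) / (f + 1 - A)
    diag(w) <- 1
    w <- (w + t(w)) / 2
    attr(w, "denom") <- denom
    w
}

#' Average-linkage protein dendrogram on 1 - TOM
#'
#' Agglomerative average-linkage (UPGMA) clustering of the topological
#' overlap dissimilarity. Ties in merge height are resolved by
#' lowest-index-first merging (the \code{\link[stats]{hclust}}
#' convention), so runs are reproducible.
#'
#' @param diss square symmetric dissimilarity matrix with zero diagonal
#'   (typically \code{1 - tomSimilarity(...)}).
#' @return An \code{\link[stats]{hclust}} tree.
#' @export
clusterTree <- function(diss) {
    if (anyNA(diss)) stop("dissimilarity contains NA/NaN")
    if (max(abs(diag(diss))) > 1e-12)
        stop("dissimilarity diagonal must be zero")
    stats::hclust(stats::as.dist(diss), method = "average")
}

# deepSplit 0..4 -> core-scatter cap; the gap floor is 0.75 * (1 - cap).
.DEEPSPLIT_SCATTER <- c(0.64, 0.73, 0.82, 0.91, 0.95)

#' Dynamic hybrid tree cut
#'
#' Adaptive dendrogram cutting in the spirit of the dynamic hybrid
#' method, specialized to the component-emergence view of a
#' co-expression dendrogram: scanning merges from the bottom of the
#' tree upward, a branch becomes a candidate module core at the moment
#' it first reaches \code{minModuleSize} members (both children still
#' smaller). The candidate is accepted when its core merge heights stay
#' below the \code{deepSplit}-parameterized scatter cap; members that
#' joined the candidate far above its own core band (beyond the core
#' median plus three core upper-spreads, or the minimum-gap parameter
#' if larger) are trimmed, and the candidate dissolves if trimming
#' drops it below \code{minModuleSize}. A locked core's branch then
#' keeps absorbing small side-branches (below \code{minModuleSize})
#' while the merge height stays in the lower half of the reference
#' height range; everything else stays unassigned (label 0).
#'
#' The \code{deepSplit} level 0--4 maps to a core-scatter cap of 0.64,
#' 0.73, 0.82, 0.91, 0.95 with minimum gap 0.75 * (1 - cap), both
#' relative to the [5th, 99th] percentile range of merge heights.
#' Because high soft-threshold powers compress topological overlap
#' dissimilarities toward 1 (heights differing only in late decimal
#' places), merge heights are measured on the -log10(1 - h) scale
#' whenever all heights lie in [0, 1]; the transform is monotone, so
#' the tree itself is untouched -- only the cut criteria gain
#' resolution.
#'
#' With \code{pamStage}, unassigned proteins then join the module with
#' the highest mean topological similarity (equivalently, the smallest
#' average dissimilarity), provided that similarity clears the module's
#' assignment radius: the geometric midpoint, on the log-similarity
#' scale, between the module's weakest member and the median unassigned
#' protein. Modules are relabeled 1..k in decreasing size order.
#'
#' @param tree \code{hclust} tree from \code{\link{clusterTree}}.
#' @param diss the dissimilarity the tree was built on (needed for the
#'   PAM stage).
#' @param deepSplit split sensitivity, integer 0--4.
#' @param minModuleSize smallest retained module.
#' @param pamStage run the PAM-like assignment of leftovers.
#' @return Named integer labels (0 = unassigned).
#' @export
cutDynamicHybrid <- function(tree, diss, deepSplit = 4L,
                             minModuleSize = 25L, pamStage = TRUE) {
    stopifnot(deepSplit %in% 0:4, minModuleSize >= 1L)
    n <- length(tree$order)
    labName <- tree$labels %||% as.character(seq_len(n))
    labels <- stats::setNames(integer(n), labName)
    if (minModuleSize > n) {
        warning("minModuleSize exceeds the number of proteins; ",
                "all unassigned")
        return(labels)
    }
    h <- tree$height
    if (all(h >= 0 & h <= 1))
        h <- -log10(pmax(1 - h, .Machine$double.eps))
    refLow <- stats::quantile(h, 0.05, names = FALSE)
    refHigh <- stats::quantile(h, 0.99, names = FALSE)
    rng <- refHigh - refLow
    maxCoreScatter <- .DEEPSPLIT_SCATTER[deepSplit + 1L]
    if (rng <= 0) {
        # all merges at one height: a single undifferentiated cluster
        labels[] <- 1L
        return(.pamAndRank(labels, diss, pamStage))
    }
    scatterAbs <- refLow + maxCoreScatter * rng
    gapAbs <- 0.75 * (1 - maxCoreScatter) * rng
    absorbAbs <- refLow + rng / 2

    nm <- nrow(tree$merge)
    members <- vector("list", nm)
    joinH <- vector("list", nm)   # height at which each member joined
    hsort <- vector("list", nm)   # sorted internal merge heights
    branchLab <- integer(nm)      # module carried by branch; -1 = dead
    cap <- max(minModuleSize - 1L, 1L)
    nextLab <- 0L
    for (i in seq_len(nm)) {   # hclust merges come in ascending height
        a <- tree$merge[i, 1L]; b <- tree$merge[i, 2L]
        sa <- if (a < 0) 1L else length(members[[a]])
        sb <- if (b < 0) 1L else length(members[[b]])
        la <- if (a < 0) 0L else branchLab[a]
        lb <- if (b < 0) 0L else branchLab[b]
        ma <- if (a < 0) -a else members[[a]]
        mb <- if (b < 0) -b else members[[b]]
        members[[i]] <- c(ma, mb)
        joinH[[i]] <- c(if (a < 0) h[i] else joinH[[a]],
                        if (b < 0) h[i] else joinH[[b]])
        hsort[[i]] <- sort(c(if (a > 0) hsort[[a]] else numeric(0),
                             if (b > 0) hsort[[b]] else numeric(0),
                             h[i]))
        if (la > 0L && lb > 0L || la < 0L || lb < 0L) {
            branchLab[i] <- -1L   # two locked modules met: branch dead
        } else if (la > 0L || lb > 0L) {
            lockLab <- max(la, lb)
            othSize <- if (la > 0L) sb else sa
            othMemb <- if (la > 0L) mb else ma
            branchLab[i] <- lockLab
            if (othSize < minModuleSize && h[i] <= absorbAbs) {
                labels[othMemb[labels[othMemb] == 0L]] <- lockLab
            } else if (othSize >= minModuleSize) {
                branchLab[i] <- -1L
            }
        } else if (sa + sb >= minModuleSize &&
                   max(sa, sb) < minModuleSize) {
            # first crossing of minModuleSize: candidate module core
            core <- hsort[[i]][seq_len(min(cap, length(hsort[[i]])))]
            if (mean(core) <= scatterAbs) {
                med <- stats::median(core)
                q90 <- stats::quantile(core, 0.9, names = FALSE)
                ceilH <- med + max(3 * (q90 - med), gapAbs)
                keep <- members[[i]][joinH[[i]] <= ceilH &
                                         labels[members[[i]]] == 0L]
                if (length(keep) >= minModuleSize) {
                    nextLab <- nextLab + 1L
                    labels[keep] <- nextLab
                    branchLab[i] <- nextLab
                }
            }
        }
    }
    .pamAndRank(labels, diss, pamStage)
}

# PAM-like stage: each unassigned object joins the module with the
# highest mean similarity (1 - mean dissimilarity), if that similarity
# clears the module's assignment radius -- on the log scale, the
# midpoint between the weakest member and the median unassigned object.
.pamAndRank <- function(labels, diss, pamStage) {
    diss <- as.matrix(diss)
    floorS <- 1e-15
    if (pamStage && any(labels == 0L) && any(labels > 0L)) {
        mods <- sort(unique(labels[labels > 0L]))
        lS <- vapply(mods, function(m) {
            s <- 1 - rowMeans(diss[, labels == m, drop = FALSE])
            log10(pmax(s, floorS))
        }, numeric(length(labels)))
        lS <- matrix(lS, ncol = length(mods))
        minMember <- vapply(seq_along(mods), function(j)
            min(lS[labels == mods[j], j]), 0)
        un <- which(labels == 0L)
        bestj <- apply(lS[un, , drop = FALSE], 1L, which.max)
        bestS <- lS[cbind(un, bestj)]
        medUn <- stats::median(bestS)
        accept <- bestS >= (minMember[bestj] + medUn) / 2 &
            bestS > log10(floorS)
        labels[un[accept]] <- mods[bestj[accept]]
    }
    .rankBySize(labels)
}

# renumber modules 1..k by decreasing size (ties: previous label order)
.rankBySize <- function(labels) {
    old <- labels[labels > 0L]
    if (!length(old)) return(labels)
    tab <- table(old)
    ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
    map <- stats::setNames(seq_along(ord), ord)
    labels[labels > 0L] <- map[as.character(old)]
    labels
}

#' Module eigenproteins (first principal components)
#'
#' Each module is summarized by the first right-singular vector of its
#' standardized protein x sample matrix (every profile z-scored across
#' samples): a unit-norm sample-space pattern, sign-oriented to
#' correlate positively with the module-average profile (falling back
#' to the highest-|loading| member when the average cancels out).
#' \code{varExplained} is the first squared singular value over the
#' total. A module with a single protein uses that standardized profile
#' directly and is flagged.
#'
#' @param X complete proteins x samples log2 abundance matrix.
#' @param labels named integer module labels (0 ignored).
#' @return List with \code{ME} (modules x samples, rows "M1"..),
#'   \code{varExplained}, and \code{flagged} (modules summarized by a
#'   single profile).
#' @export
moduleEigenproteins <- function(X, labels) {
    labels <- labels[intersect(names(labels), rownames(X))]
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids))
        return(list(ME = matrix(0, 0, ncol(X),
                                dimnames = list(NULL, colnames(X))),
                    varExplained = numeric(0), flagged = character(0)))
    ME <- matrix(NA_real_, length(ids), ncol(X),
                 dimnames = list(paste0("M", ids), colnames(X)))
    ve <- stats::setNames(numeric(length(ids)), rownames(ME))
    flagged <- character(0)
    for (j in seq_along(ids)) {
        rows <- names(labels)[labels == ids[j]]
        Z <- .zscoreRows(X[rows, , drop = FALSE])
        if (nrow(Z) < 2L) {
            ME[j, ] <- Z[1L, ] / sqrt(sum(Z[1L, ]^2))
            ve[j] <- 1
            flagged <- c(flagged, rownames(ME)[j])
            next
        }
        s <- svd(Z, nu = min(2L, nrow(Z)), nv = 1L)
        e <- s$v[, 1L]
        ref <- colMeans(Z)
        if (sqrt(sum(ref^2)) < 1e-10)
            ref <- Z[which.max(abs(s$u[, 1L])), ]
        if (sum(e * ref) < 0) e <- -e
        ME[j, ] <- e
        ve[j] <- s$d[1L]^2 / sum(s$d^2)
    }
    list(ME = ME, varExplained = ve, flagged = flagged)
}

.zscoreRows <- function(X) {
    mu <- rowMeans(X)
    sd <- apply(X, 1L, stats::sd)
    sd[sd == 0] <- 1  # constant profile -> all-zero z-scores
    (X - mu) / sd
}

#' kME: module membership of every protein in every module
#'
#' kME(p, m) is the Pearson correlation between protein p's profile and
#' module m's eigenprotein; its p-value comes from the Student transform
#' t = r sqrt((n-2)/(1-r^2)) with n-2 df, two-sided. Constant profiles
#' give \code{NA}.
#'
#' @param X proteins x samples matrix.
#' @param ME modules x samples eigenprotein matrix.
#' @return List with matrices \code{kME} and \code{p} (proteins x
#'   modules).
#' @export
kmeTable <- function(X, ME) {
    stopifnot(ncol(X) == ncol(ME), ncol(X) >= 3L)
    r <- suppressWarnings(stats::cor(t(X), t(ME)))
    n <- ncol(X)
    p <- corPvalue(r, n)
    list(kME = r, p = p)
}

#' Student p-value for a correlation
#'
#' Two-sided p from t = r sqrt((n-2)/(1-r^2)) on n-2 df; |r| = 1 gives
#' p = 0, undefined r gives NA.
#'
#' @param r correlation(s).
#' @param n number of observations.
#' @export
corPvalue <- function(r, n) {
    t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
    p[abs(r) >= 1] <- 0
    p[is.na(r)] <- NA_real_
    if (is.matrix(r)) dimnames(p) <- dimnames(r)
    p
}

#' Merge modules with similar eigenproteins
#'
#' Eigenproteins are clustered by average linkage on 1 - cor; all
#' modules within a subtree of height strictly below
#' \code{mergeCutHeight} merge, eigenproteins are recomputed, and the
#' step repeats until no merge occurs.
#'
#' @param X complete proteins x samples matrix.
#' @param labels named integer module labels.
#' @param mergeCutHeight dissimilarity threshold (default 0.07, i.e.
#'   eigenprotein correlation above 0.93 merges).
#' @return List with final \code{labels} (renumbered by size) and a
#'   \code{history} data.frame (iteration, from, into).
#' @export
mergeCloseModules <- function(X, labels, mergeCutHeight = 0.07) {
    history <- data.frame(iteration = integer(0), from = integer(0),
                          into = integer(0))
    if (mergeCutHeight <= 0)   # merging switched off
        return(list(labels = labels, history = history))
    iter <- 0L
    repeat {
        ids <- sort(unique(labels[labels > 0L]))
        if (length(ids) < 2L) break
        ME <- moduleEigenproteins(X, labels)$ME
        d <- 1 - stats::cor(t(ME))
        hc <- stats::hclust(stats::as.dist(d), method = "average")
        grp <- stats::cutree(hc, h = mergeCutHeight * (1 - 1e-9))
        if (max(grp) == length(ids)) break
        iter <- iter + 1L
        for (g in unique(grp)) {
            mods <- ids[grp == g]
            if (length(mods) < 2L) next
            into <- min(mods)
            for (from in setdiff(mods, into)) {
                labels[labels == from] <- into
                history <- rbind(history,
                                 data.frame(iteration = iter, from = from,
                                            into = into))
            }
        }
    }
    list(labels = .rankBySize(labels), history = history)
}

#' Single-pass kME reassignment
#'
#' A protein moves to a foreign module when its kME there exceeds the
#' kME to its own module and the foreign kME's Student p-value is below
#' \code{threshold}. Decisions use the kME table of the incoming
#' labeling (single pass); eigenproteins are recomputed afterwards.
#' \code{threshold = 0} disables all moves.
#'
#' @param X complete proteins x samples matrix.
#' @param labels named integer module labels.
#' @param threshold reassignment p-value threshold (default 0.05).
#' @return List with \code{labels} (renumbered by size) and \code{moves}
#'   (data.frame protein, from, to, kME_from, kME_to, p).
#' @export
reassignByKME <- function(X, labels, threshold = 0.05) {
    moves <- data.frame(protein = character(0), from = integer(0),
                        to = integer(0), kME_from = numeric(0),
                        kME_to = numeric(0), p = numeric(0))
    ids <- sort(unique(labels[labels > 0L]))
    if (length(ids) >= 2L && threshold > 0) {
        ME <- moduleEigenproteins(X, labels)$ME
        km <- kmeTable(X[names(labels), , drop = FALSE], ME)
        for (p in names(labels)[labels > 0L]) {
            own <- labels[[p]]
            r <- km$kME[p, ]
            foreign <- setdiff(seq_along(ids), match(own, ids))
            best <- foreign[which.max(r[foreign])]
            if (is.na(r[best])) next
            if (r[best] > r[match(own, ids)] &&
                km$p[p, best] < threshold) {
                moves <- rbind(moves, data.frame(
                    protein = p, from = own, to = ids[best],
                    kME_from = unname(r[match(own, ids)]),
                    kME_to = unname(r[best]), p = unname(km$p[p, best])))
            }
        }
        if (nrow(moves))
            labels[moves$protein] <- moves$to
    }
    list(labels = .rankBySize(labels), moves = moves)
}

#' Map half-missing proteins onto existing modules
#'
#' Proteins quantified in only one batch never enter network
#' construction (they have no cross-batch covariance); afterwards each
#' one is correlated -- by biweight midcorrelation over its cognate
#' (quantified) samples -- with every module eigenprotein restricted to
#' those samples, and assigned to the top-correlated module. The
#' assignment carries the correlation, n (8 in the standard design) and
#' a reduced-confidence flag. A minimum-correlation floor can be
#' requested via \code{minKME}; by default every protein is assigned to
#' its argmax, even when anti-correlated (flagged). Proteins with fewer
#' than 3 cognate samples are left unassigned.
#'
#' @param x a \linkS4class{ProteomeSet}.
#' @param ME modules x samples eigenprotein matrix (full design).
#' @param minKME optional minimum correlation to accept an assignment.
#' @return data.frame (protein, module, kME, n, low_confidence,
#'   anti_correlated).
#' @export
mapHalfMissing <- function(x, ME, minKME = NULL) {
    hm <- halfMissingProteins(x)
    out <- data.frame(protein = character(0), module = character(0),
                      kME = numeric(0), n = integer(0),
                      low_confidence = logical(0),
                      anti_correlated = logical(0))
    if (!length(hm) || nrow(ME) == 0L) return(out)
    V <- log2Abundance(x)
    for (p in hm) {
        smp <- colnames(V)[quantMask(x)[p, ]]
        if (length(smp) < 3L) {
            out <- rbind(out, data.frame(
                protein = p, module = "M0", kME = NA_real_,
                n = length(smp), low_confidence = TRUE,
                anti_correlated = NA))
            next
        }
        r <- vapply(rownames(ME), function(m)
            bicor(V[p, smp], ME[m, smp], pairwiseComplete = TRUE), 0)
        best <- which.max(r)
        assigned <- rownames(ME)[best]
        if (!is.null(minKME) && (is.na(r[best]) || r[best] < minKME))
            assigned <- "M0"
        out <- rbind(out, data.frame(
            protein = p, module = assigned, kME = unname(r[best]),
            n = length(smp), low_confidence = TRUE,
            anti_correlated = isTRUE(unname(r[best]) < 0)))
    }
    rownames(out) <- NULL
    out
}

#' Build the full co-expression network
#'
#' The network stage end to end, on the complete proteins only:
#' correlation (Pearson by default), soft-threshold adjacency
#' (beta = 29, unsigned), topological overlap ("mean" denominator),
#' average-linkage clustering of 1 - TOM, dynamic hybrid cut
#' (deepSplit = 4, minimum module size 25, PAM stage), eigenprotein
#' merge at cut height 0.07, single-pass kME reassignment at p < 0.05,
#' and finally post-hoc mapping of half-missing proteins. Deterministic
#' for fixed input and config.
#'
#' @param x a \linkS4class{ProteomeSet}.
#' @param config a \code{\link{runConfig}}.
#' @return A \linkS4class{ModuleSet}.
#' @examples
#' sim <- simulateProteome(simConfig(nModules = 2, proteinsPerModule = 30,
#'                                   nBackground = 30, nHalfMissing = 6))
#' net <- buildNetwork(sim$proteome,
#'                     runConfig(minModuleSize = 10, beta = 6))
#' net
#' @export
buildNetwork <- function(x, config = runConfig()) {
    X <- abundanceMatrix(x, complete = TRUE)
    corr <- correlationMatrix(X, method = config$networkCor)
    A <- adjacencyMatrix(corr, beta = config$beta,
                         networkType = config$networkType)
    tom <- tomSimilarity(A, denom = config$tomDenom)
    diss <- 1 - tom
    diag(diss) <- 0
    tree <- clusterTree(diss)
    labels <- cutDynamicHybrid(tree, diss,
                               deepSplit = config$deepSplit,
                               minModuleSize = config$minModuleSize,
                               pamStage = config$pamStage)
    merged <- mergeCloseModules(X, labels, config$mergeCutHeight)
    re <- reassignByKME(X, merged$labels, config$reassignThreshold)
    labels <- re$labels
    ep <- moduleEigenproteins(X, labels)
    km <- kmeTable(X, ep$ME)
    hm <- mapHalfMissing(x, ep$ME)
    new("ModuleSet",
        labels = labels,
        eigenproteins = ep$ME,
        varExplained = ep$varExplained,
        kME = km$kME,
        kMEPvalue = km$p,
        mergeHistory = merged$history,
        reassignments = re$moves,
        halfMissing = hm,
        params = unclass(config))
}
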