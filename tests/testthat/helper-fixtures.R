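# Shared fixtures and independent oracles, all built in code.

# Minimal valid ProteomeSet: p proteins x n samples with the standard
# 2x2 design when n = 16, otherwise a single-batch layout.
makeProteome <- function(values) {
    n <- ncol(values)
    if (n == 16L) {
        sd <- expand.grid(replicate = 1:4,
                          genotype = c("WT", "KO"),
                          age_group = c("young", "old"),
                          stringsAsFactors = FALSE)
        sd$batch <- paste0("batch_", sd$age_group)
    } else {
        sd <- data.frame(replicate = seq_len(n),
                         genotype = rep(c("WT", "KO"), length.out = n),
                         age_group = "young", batch = "b1",
                         stringsAsFactors = FALSE)
    }
    rownames(sd) <- colnames(values)
    ProteomeSet(values, sd)
}

randomProteome <- function(p, n = 16L, seed = 1L) {
    set.seed(seed)
    v <- matrix(rnorm(p * n, mean = 20), p, n,
                dimnames = list(sprintf("pr%03d", seq_len(p)),
                                sprintf("s%02d", seq_len(n))))
    makeProteome(v)
}

# Small simulation used across tests (fast but structured).
smallSim <- function(seed = 1L, ...) {
    simulateProteome(simConfig(
        nModules = 2L, proteinsPerModule = 15L,
        nBackground = 30L, nHalfMissing = 6L,
        markerOverlap = list(
            Microglia = c(module = 1, fraction = 0.8, size = 15),
            Astrocyte = c(module = 2, fraction = 0.4, size = 15)),
        seed = seed, ...))
}

# --- independent oracles -------------------------------------------------

# Triple-loop topological overlap, written directly from the definition.
naiveTOM <- function(A, denom) {
    n <- nrow(A)
    w <- matrix(0, n, n)
    k <- numeric(n)
    for (i in seq_len(n)) k[i] <- sum(A[i, -i])
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) { w[i, j] <- 1; next }
            l <- 0
            for (u in seq_len(n)) if (u != i && u != j)
                l <- l + A[i, u] * A[u, j]
            f <- if (denom == "min") min(k[i], k[j]) else (k[i] + k[j]) / 2
            w[i, j] <- (l + A[i, j]) / (f + 1 - A[i, j])
        }
    }
    w
}

# Naive O(n^3) average-linkage agglomeration; returns sorted merge heights.
naiveUPGMAHeights <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    active <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(active) > 1L) {
        best <- c(NA, NA); bestd <- Inf
        for (i in seq_len(length(active) - 1L)) {
            for (j in (i + 1L):length(active)) {
                dd <- mean(d[active[[i]], active[[j]]])
                if (dd < bestd) { bestd <- dd; best <- c(i, j) }
            }
        }
        heights <- c(heights, bestd)
        merged <- c(active[[best[1L]]], active[[best[2L]]])
        active <- active[-best]
        active[[length(active) + 1L]] <- merged
    }
    sort(heights)
}

# Exact hypergeometric upper tail by direct enumeration of the support.
enumHyperTail <- function(r, R, N, n) {
    lo <- max(0L, n - (N - R)); hi <- min(n, R)
    support <- lo:hi
    mass <- choose(R, support) * choose(N - R, n - support) / choose(N, n)
    sum(mass[support >= r])
}

# Symmetric two-block dissimilarity: within wd, between bd.
blockDiss <- function(sizes, wd = 0.05, bd = 0.95) {
    n <- sum(sizes)
    d <- matrix(bd, n, n)
    at <- cumsum(c(0, sizes))
    for (b in seq_along(sizes)) {
        idx <- (at[b] + 1L):at[b + 1L]
        d[idx, idx] <- wd
    }
    diag(d) <- 0
    dimnames(d) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
    d
}
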