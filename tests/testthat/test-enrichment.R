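test_that("module-trait correlation hits the reference points", {
    si <- sampleInfo(simulateProteome(simConfig(nModules = 1,
        proteinsPerModule = 2, nBackground = 0, nHalfMissing = 0,
        markerOverlap = list()))$proteome)
    geno <- as.numeric(si$genotype == "KO")
    ME <- rbind(M1 = geno)
    colnames(ME) <- rownames(si)
    # this ME *is* the binary trait, so it is constant inside one
    # stratum and triggers the documented mad = 0 fallback there
    mt <- suppressWarnings(moduleTrait(ME, si))
    row <- mt[mt$trait == "genotype_KO" & mt$stratum == "all", ]
    expect_equal(row$r, 1, tolerance = 1e-10)
    expect_lt(row$p, 1e-10)
    expect_identical(row$stars, "****")
    # genotype is constant within a genotype stratum of the age trait? no:
    # age is constant within an age stratum -> NA there
    ageRows <- mt[mt$trait == "age_old", ]
    expect_true(all(is.finite(ageRows$r[ageRows$stratum == "all"])))
    # strata restrict n
    expect_identical(unique(mt$n[mt$stratum %in% c("young", "old")]), 8L)
})

test_that("trait p-values follow the Student transform", {
    # r = 0.9, n = 8: t = 0.9 * sqrt(6 / 0.19)
    t <- 0.9 * sqrt(6 / 0.19)
    expect_equal(t, 5.0576, tolerance = 1e-4)
    expect_equal(corPvalue(0.9, 8), 2 * pt(t, 6, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("Fisher enrichment equals exact hypergeometric enumeration", {
    tab <- fisherCellType(list(M1 = paste0("g", 1:3)),
                          list(S = paste0("g", 1:3)),
                          universe = paste0("g", 1:10))
    expect_equal(tab$fisher_p, 1 / 120, tolerance = 1e-12)
    # r = 0 -> p = 1 (total mass); full overlap degenerate -> p = 1
    tab0 <- fisherCellType(list(M1 = paste0("g", 1:3)),
                           list(S = paste0("g", 8:10)),
                           universe = paste0("g", 1:10))
    expect_equal(tab0$fisher_p, 1)
    tabf <- fisherCellType(list(M1 = paste0("g", 1:4)),
                           list(S = paste0("g", 1:4)),
                           universe = paste0("g", 1:4))
    expect_equal(tabf$fisher_p, 1)
    # random instances vs the enumeration oracle
    set.seed(12)
    for (i in 1:20) {
        N <- sample(5:60, 1)
        R <- sample(1:N, 1); n <- sample(1:N, 1)
        uni <- paste0("u", seq_len(N))
        set <- sample(uni, R); mod <- sample(uni, n)
        r <- length(intersect(set, mod))
        tab <- fisherCellType(list(M = mod), list(S = set), universe = uni)
        expect_equal(tab$fisher_p, enumHyperTail(r, R, N, n),
                     tolerance = 1e-12)
    }
})

test_that("Z-score over-representation follows the corrected formula", {
    mkTab <- function(N, R, n, r) {
        uni <- paste0("u", seq_len(N))
        zscoreEnrichment(list(M = uni[seq_len(n)]),
                         list(S = c(uni[seq_len(r)],
                                    uni[n + seq_len(R - r)])),
                         universe = uni)
    }
    tab <- mkTab(100, 10, 20, 6)
    expect_equal(tab$z, (6 - 2) / sqrt(20 * 0.1 * 0.9 * (1 - 19 / 99)),
                 tolerance = 1e-12)
    expect_equal(tab$z_p_approx, pnorm(tab$z, lower.tail = FALSE),
                 tolerance = 1e-12)
    # centering and sign
    expect_equal(mkTab(100, 10, 20, 2)$z, 0, tolerance = 1e-12)
    expect_lt(mkTab(100, 10, 20, 0)$z, 0)
})

test_that("Z and Fisher p agree in ordering", {
    # within fixed margins (N, R, n), sweeping the overlap r over its
    # support: strictly larger Z must give strictly smaller Fisher p
    set.seed(13)
    for (i in 1:10) {
        N <- sample(30:80, 1)
        R <- sample(3:(N - 3), 1); n <- sample(3:(N - 3), 1)
        uni <- paste0("u", seq_len(N))
        lo <- max(0, n - (N - R)); hi <- min(n, R)
        zs <- ps <- numeric(0)
        for (r in lo:hi) {
            mod <- c(uni[seq_len(r)], uni[R + seq_len(n - r)])
            tab <- fisherCellType(list(M = mod),
                                  list(S = uni[seq_len(R)]),
                                  universe = uni)
            zs <- c(zs, tab$z); ps <- c(ps, tab$fisher_p)
        }
        expect_true(all(diff(zs) > 0))
        expect_true(all(diff(ps) <= 0))
    }
    # across random instances the rank agreement stays high once the
    # all-ties p = 1 instances are set aside
    z <- c(); fp <- c()
    for (i in 1:80) {
        N <- sample(30:80, 1)
        R <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
        uni <- paste0("u", seq_len(N))
        tab <- fisherCellType(list(M = sample(uni, n)),
                              list(S = sample(uni, R)), universe = uni)
        z <- c(z, tab$z); fp <- c(fp, tab$fisher_p)
    }
    keep <- fp < 1
    expect_gte(cor(z[keep], -fp[keep], method = "spearman"), 0.9)
})

test_that("BH adjustment is the step-up procedure, order invariant", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.42), 0.42)
    p <- rep(0.2, 5)
    expect_equal(bhAdjust(p), p)
    set.seed(14)
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(q >= p))
    perm <- sample(50)
    expect_equal(bhAdjust(p[perm]), q[perm], tolerance = 1e-15)
    o <- order(p)
    expect_false(is.unsorted(q[o]))
})

test_that("enrichment defaults to the network-protein universe", {
    sim <- smallSim(seed = 7L)
    net <- buildNetwork(sim$proteome, runConfig(minModuleSize = 10L))
    tab <- fisherCellType(net, sim$markers)
    expect_identical(unique(tab$N), length(moduleLabels(net)))
    expect_true(all(tab$r <= pmin(tab$n, tab$R)))
    expect_true(all(tab$bh_p >= tab$fisher_p - 1e-15))
    # per-set BH family on request
    tab2 <- fisherCellType(net, sim$markers, family = "perSet")
    expect_identical(tab2$fisher_p, tab$fisher_p)
})

test_that("Cohen's kappa matches the 2x2 hand computation", {
    # N = 20, |A| = 8, |B| = 8, overlap 6: a=6, b=2, c=2, d=10
    po <- 16 / 20
    pe <- (8 * 8 + 12 * 12) / 400
    uni <- paste0("g", 1:20)
    a <- uni %in% uni[1:8]
    b <- uni %in% uni[c(1:6, 9:10)]
    expect_equal(cohenKappa(a, b), (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_equal(cohenKappa(a, a), 1)
    # disjoint memberships covering the universe -> kappa <= 0
    expect_lte(cohenKappa(uni %in% uni[1:10], uni %in% uni[11:20]), 0)
})

test_that("kappa clustering groups by membership similarity at 0.3", {
    uni <- paste0("g", 1:20)
    sets <- list(A = uni[1:8], A2 = uni[c(1:7, 9)],
                 B = uni[11:18], C = uni[c(1, 10, 19, 20)])
    p <- c(A = 0.01, A2 = 0.002, B = 0.03, C = 0.5)
    tc <- kappaCluster(sets, uni, kappaThreshold = 0.3, p = p)
    expect_identical(tc$clusters[["A"]], tc$clusters[["A2"]])
    expect_false(tc$clusters[["A"]] == tc$clusters[["B"]])
    repA <- tc$representatives$term[
        tc$representatives$cluster == tc$clusters[["A"]]]
    expect_identical(repA, "A2")   # smallest p represents the cluster
    expect_equal(diag(tc$kappa), rep(1, 4), ignore_attr = TRUE)
    expect_equal(tc$kappa, t(tc$kappa))
    # identical memberships: kappa 1, one cluster
    tc2 <- kappaCluster(list(X = uni[1:5], Y = uni[1:5]), uni)
    expect_equal(tc2$kappa["X", "Y"], 1)
    expect_identical(tc2$clusters[["X"]], tc2$clusters[["Y"]])
})
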