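test_that("soft-threshold adjacency has the right functional form", {
    r <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3, 3)
    a <- adjacencyMatrix(r, beta = 2, networkType = "unsigned")
    expect_equal(a[1, 2], 0.25)
    expect_equal(a[1, 3], 1)
    expect_equal(diag(a), rep(0, 3))
    s <- adjacencyMatrix(r, beta = 5, networkType = "signed")
    expect_equal(s[1, 3], 0)          # r = -1 -> 0 in a signed network
    expect_equal(s[1, 2], 0.75^5)
})

test_that("topological overlap closed forms hold", {
    A0 <- matrix(0, 4, 4)
    w0 <- tomSimilarity(A0, "mean")
    expect_equal(w0[upper.tri(w0)], rep(0, 6))
    expect_equal(diag(w0), rep(1, 4))
    A1 <- matrix(1, 5, 5); diag(A1) <- 0
    for (d in c("min", "mean"))
        expect_equal(unique(as.vector(tomSimilarity(A1, d))), 1)
    # 3-node worked example, mean denominator
    A <- matrix(0, 3, 3)
    A[1, 2] <- A[2, 1] <- 0.8
    A[1, 3] <- A[3, 1] <- 0.6
    A[2, 3] <- A[3, 2] <- 0.4
    w <- tomSimilarity(A, "mean")
    expect_equal(w[1, 2], (0.6 * 0.4 + 0.8) / (mean(c(1.4, 1.2)) + 1 - 0.8),
                 tolerance = 1e-12)
})

test_that("TOM equals the triple-loop oracle on random graphs", {
    set.seed(21)
    for (i in 1:5) {
        A <- matrix(runif(20 * 20), 20, 20)
        A <- (A + t(A)) / 2; diag(A) <- 0
        for (d in c("min", "mean")) {
            w <- tomSimilarity(A, d)
            expect_equal(unclass(w), naiveTOM(A, d), tolerance = 1e-12,
                         ignore_attr = TRUE)
            expect_true(all(w <= 1 + 1e-12 & w >= 0))
        }
    }
    expect_error(tomSimilarity(matrix(c(0, 2, 2, 0), 2, 2)), "0, 1")
})

test_that("average-linkage tree matches block structure and a naive oracle", {
    d <- blockDiss(c(3, 3), wd = 0, bd = 1)
    tr <- clusterTree(d)
    expect_equal(max(tr$height), 1)          # blocks join last at 1
    expect_equal(sort(tr$height)[1:4], rep(0, 4))
    d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3)
    tr3 <- clusterTree(d3)
    expect_equal(tr3$height, c(0.1, 0.9))
    expect_identical(sort(tr3$merge[1, ]), c(-2L, -1L))
    set.seed(33)
    for (i in 1:3) {
        m <- matrix(runif(15 * 15), 15, 15)
        m <- (m + t(m)) / 2; diag(m) <- 0
        expect_equal(sort(clusterTree(m)$height), naiveUPGMAHeights(m),
                     tolerance = 1e-12)
    }
    dn <- d; dn[1, 2] <- NaN; dn[2, 1] <- NaN
    expect_error(clusterTree(dn), "NA")
})

test_that("two clean blocks cut into exactly two full modules", {
    d <- blockDiss(c(30, 30))
    tr <- clusterTree(d)
    lab <- cutDynamicHybrid(tr, d, minModuleSize = 25)
    expect_identical(sort(unique(lab)), c(1L, 2L))
    expect_identical(as.vector(table(lab)), c(30L, 30L))
    expect_identical(sum(lab == 0L), 0L)
})

test_that("a block below minimum size dissolves to unassigned", {
    set.seed(2)
    nb <- 24L; nn <- 15L; N <- nb + nn
    d <- matrix(runif(N * N, 0.85, 0.99), N, N)
    d <- (d + t(d)) / 2
    d[1:nb, 1:nb] <- 0.05     # the tight block, one short of minimum
    diag(d) <- 0
    dimnames(d) <- list(paste0("x", 1:N), paste0("x", 1:N))
    lab <- cutDynamicHybrid(clusterTree(d), d, minModuleSize = 25)
    expect_identical(sum(lab > 0L), 0L)
})

test_that("minModuleSize above n leaves everything unassigned with warning", {
    d <- blockDiss(c(5, 5))
    expect_warning(lab <- cutDynamicHybrid(clusterTree(d), d,
                                           minModuleSize = 50), "unassigned")
    expect_identical(sum(lab), 0L)
})

test_that("eigenproteins summarize modules as first principal components", {
    n <- 12
    prof <- sin(seq_len(n))
    X <- rbind(p1 = 2 * prof + 5, p2 = 3 * prof - 1, p3 = 0.5 * prof)
    colnames(X) <- paste0("s", seq_len(n))
    lab <- c(p1 = 1L, p2 = 1L, p3 = 1L)
    ep <- moduleEigenproteins(X, lab)
    z <- as.vector(scale(prof)); z <- z / sqrt(sum(z^2))
    expect_equal(abs(as.vector(ep$ME["M1", ])), abs(z), tolerance = 1e-10)
    expect_gt(cor(ep$ME["M1", ], prof), 0)      # oriented with the mean
    expect_equal(unname(ep$varExplained["M1"]), 1, tolerance = 1e-10)
})

test_that("two anti-correlated profiles still give var explained 1", {
    n <- 10
    prof <- as.vector(scale(cos(seq_len(n))))
    X <- rbind(up = 2 * prof, down = -prof + 3)
    colnames(X) <- paste0("s", seq_len(n))
    ep <- moduleEigenproteins(X, c(up = 1L, down = 1L))
    expect_equal(unname(ep$varExplained["M1"]), 1, tolerance = 1e-10)
    # orientation follows the dominant-loading member
    expect_gt(abs(cor(ep$ME["M1", ], prof)), 0.999)
})

test_that("var explained beats any random unit summary vector", {
    set.seed(55)
    X <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
    lab <- setNames(rep(1L, 20), rownames(X))
    ep <- moduleEigenproteins(X, lab)
    Z <- t(scale(t(X)))
    total <- sum(Z^2)
    for (i in 1:100) {
        v <- rnorm(10); v <- v / sqrt(sum(v^2))
        expect_lte(sum((Z %*% v)^2) / total,
                   unname(ep$varExplained) + 1e-10)
    }
    # var explained also bounds the mean squared kME of the members
    km <- kmeTable(X, ep$ME)
    expect_gte(unname(ep$varExplained) + 1e-10, mean(km$kME^2))
})

test_that("kME and its Student p behave at the reference points", {
    set.seed(66)
    ME <- matrix(rnorm(16), 1, 16,
                 dimnames = list("M1", sprintf("s%02d", 1:16)))
    X <- rbind(same = ME[1, ], other = rnorm(16))
    km <- kmeTable(X, ME)
    expect_equal(unname(km$kME["same", "M1"]), 1, tolerance = 1e-12)
    expect_equal(unname(km$p["same", "M1"]), 0)
    # exactly orthogonal profile: r = 0 -> p = 1
    expect_equal(corPvalue(0, 16), 1)
    # r = 0.8, n = 16: t = 0.8 * sqrt(14 / 0.36)
    t <- 0.8 * sqrt(14 / 0.36)
    expect_equal(t, 4.988877, tolerance = 1e-6)
    expect_equal(corPvalue(0.8, 16), 2 * pt(t, 14, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("module merging follows the eigenprotein dissimilarity cut", {
    n <- 16
    set.seed(77)
    z1 <- as.vector(scale(rnorm(n)))
    z2 <- as.vector(scale(residuals(lm(rnorm(n) ~ z1))))
    mkX <- function(rho) {
        v2 <- rho * z1 + sqrt(1 - rho^2) * z2   # cor(z1, v2) = rho exactly
        X <- rbind(t(sapply(1:6, function(i) z1 * (1 + 0.01 * i))),
                   t(sapply(1:6, function(i) v2 * (1 + 0.01 * i))))
        dimnames(X) <- list(paste0("p", 1:12), paste0("s", 1:n))
        X
    }
    lab <- setNames(rep(1:2, each = 6L), paste0("p", 1:12))
    # cor 0.95 -> dissimilarity 0.05 < 0.07: merged
    mg <- mergeCloseModules(mkX(0.95), lab, 0.07)
    expect_identical(max(mg$labels), 1L)
    expect_identical(nrow(mg$history), 1L)
    # cor 0.90 -> dissimilarity 0.10 > 0.07: not merged
    mg2 <- mergeCloseModules(mkX(0.90), lab, 0.07)
    expect_identical(max(mg2$labels), 2L)
    expect_identical(nrow(mg2$history), 0L)
    # identical eigenproteins always merge
    mg3 <- mergeCloseModules(mkX(1), lab, 0.07)
    expect_identical(max(mg3$labels), 1L)
    # switch-off: cut height 0 never merges
    mg4 <- mergeCloseModules(mkX(1), lab, 0)
    expect_identical(max(mg4$labels), 2L)
})

test_that("kME reassignment moves dominated proteins, single pass", {
    set.seed(88)
    n <- 16
    e1 <- as.vector(scale(rnorm(n)))
    e2 <- as.vector(scale(residuals(lm(rnorm(n) ~ e1))))
    X <- rbind(t(sapply(1:5, function(i) e1 + rnorm(n, sd = 0.1))),
               t(sapply(1:5, function(i) e2 + rnorm(n, sd = 0.1))),
               stray = e2 + rnorm(n, sd = 0.05))
    dimnames(X) <- list(c(paste0("a", 1:5), paste0("b", 1:5), "stray"),
                        paste0("s", 1:n))
    lab <- setNames(c(rep(1L, 5), rep(2L, 5), 1L), rownames(X))
    re <- reassignByKME(X, lab, threshold = 0.05)
    expect_identical(nrow(re$moves), 1L)
    expect_identical(re$moves$protein, "stray")
    expect_identical(unname(re$labels["stray"]),
                     unname(re$labels[["b1"]]))
    # proteins already best in their own module stay put
    expect_identical(sum(re$labels[paste0("a", 1:5)] ==
                             re$labels[["a1"]]), 5L)
    # threshold 0 disables every move
    re0 <- reassignByKME(X, lab, threshold = 0)
    expect_identical(nrow(re0$moves), 0L)
})

test_that("null data see little reassignment", {
    ps <- randomProteome(60, n = 16, seed = 99)
    X <- abundanceMatrix(ps)
    lab <- setNames(rep(1:3, each = 20L), rownames(X))
    re <- reassignByKME(X, lab, threshold = 0.05)
    expect_lte(nrow(re$moves), 6L)   # a few percent of 60
})

test_that("half-missing proteins map to the top-correlated eigenprotein", {
    sim <- smallSim(seed = 2L)
    cfg <- runConfig(minModuleSize = 10L)
    net <- buildNetwork(sim$proteome, cfg)
    hm <- halfMissingAssignments(net)
    expect_identical(sort(hm$protein),
                     sort(halfMissingProteins(sim$proteome)))
    expect_true(all(hm$n == 8L))
    expect_true(all(hm$low_confidence))
    # a synthetic protein equal to an eigenprotein on its batch maps there
    ME <- eigenProteins(net)
    v <- log2Abundance(sim$proteome)
    young <- sampleInfo(sim$proteome)$batch == "batch_young"
    v <- rbind(v, planted = NA)
    v["planted", young] <- ME["M1", young]
    ps2 <- ProteomeSet(v, sampleInfo(sim$proteome))
    mp <- mapHalfMissing(ps2, ME)
    row <- mp[mp$protein == "planted", ]
    expect_identical(row$module, "M1")
    expect_equal(row$kME, 1, tolerance = 1e-10)
    # anti-correlated profile: still assigned to the argmax, flagged;
    # a minimum-kME floor unassigns it instead
    v["planted", young] <- -ME["M1", young] - ME["M2", young]
    ps3 <- ProteomeSet(v, sampleInfo(sim$proteome))
    mp3 <- mapHalfMissing(ps3, ME)
    row3 <- mp3[mp3$protein == "planted", ]
    expect_true(row3$module != "M0")
    expect_true(row3$anti_correlated)
    mp4 <- mapHalfMissing(ps3, ME, minKME = 0)
    expect_identical(mp4[mp4$protein == "planted", "module"], "M0")
})

test_that("the network build is deterministic and size-ranked", {
    sim <- smallSim(seed = 3L)
    cfg <- runConfig(minModuleSize = 10L)
    n1 <- buildNetwork(sim$proteome, cfg)
    n2 <- buildNetwork(sim$proteome, cfg)
    expect_identical(moduleLabels(n1), moduleLabels(n2))
    expect_equal(eigenProteins(n1), eigenProteins(n2), tolerance = 1e-12)
    sz <- moduleSizes(n1)
    expect_false(is.unsorted(rev(sz)))
    expect_identical(names(sz), paste0("M", seq_along(sz)))
})

test_that("module structure is stable under protein-order permutation", {
    sim <- smallSim(seed = 4L)
    cfg <- runConfig(minModuleSize = 10L)
    n1 <- buildNetwork(sim$proteome, cfg)
    set.seed(1)
    perm <- sample(nrow(sim$proteome))
    n2 <- buildNetwork(sim$proteome[perm, ], cfg)
    expect_identical(unname(moduleSizes(n1)), unname(moduleSizes(n2)))
    expect_identical(moduleLabels(n2)[names(moduleLabels(n1))],
                     moduleLabels(n1))
})

test_that("switch-off config reproduces the raw dynamic-cut labels", {
    sim <- smallSim(seed = 5L)
    cfg <- runConfig(minModuleSize = 10L, mergeCutHeight = 0,
                     reassignThreshold = 0)
    net <- buildNetwork(sim$proteome, cfg)
    X <- abundanceMatrix(sim$proteome)
    tom <- tomSimilarity(adjacencyMatrix(correlationMatrix(X), 29,
                                         "unsigned"), "mean")
    diss <- 1 - tom; diag(diss) <- 0
    raw <- cutDynamicHybrid(clusterTree(diss), diss, deepSplit = 4L,
                            minModuleSize = 10L)
    expect_identical(moduleLabels(net), raw)
})
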