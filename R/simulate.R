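#' Simulation settings for the two-batch 2x2 proteome design
#'
#' Describes a synthetic TMT-style experiment: 16 samples (2 genotypes x
#' 2 age groups x \code{nPerGroup} replicates, one batch per age group),
#' \code{nModules} planted co-expression modules driven by latent
#' eigenprofiles with genotype and age effects, a pool of pure-noise
#' background proteins, and a tranche of module members quantified in
#' only one batch (exactly 50\% missing). Defaults plant 5 modules of 40
#' proteins over 200 background proteins, with loadings near 1 and
#' \code{noiseSd = 0.8} log2 units so that the mean within-module
#' correlation sits near 0.6 -- tight enough that recovery is
#' well-posed, loose enough that it is not trivial.
#'
#' @param nModules number of planted modules.
#' @param proteinsPerModule complete proteins per module.
#' @param nBackground pure-noise background proteins.
#' @param nHalfMissing module-member proteins quantified in one batch
#'   only (assigned round-robin to modules and alternating batches).
#' @param nPerGroup replicates per genotype-by-age cell.
#' @param effectGenotype per-module KO-minus-WT shift of the latent
#'   eigenprofile, log2 units; recycled to \code{nModules}.
#' @param effectAge per-module old-minus-young shift, log2 units.
#' @param loadingMean,loadingSd distribution of per-protein loadings on
#'   the module eigenprofile.
#' @param noiseSd per-protein residual noise, log2 units.
#' @param markerOverlap named list: cell type -> \code{c(module, fraction,
#'   size)}; \code{fraction} of the marker set is drawn from that module,
#'   the rest from background. The default plants a strong (0.8)
#'   microglial overlap into module 1 and weaker (0.4) astrocyte,
#'   neuron and oligodendrocyte overlaps into modules 2--4, keeping
#'   only entries whose module exists.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nModules = 5L,
                      proteinsPerModule = 40L,
                      nBackground = 200L,
                      nHalfMissing = 60L,
                      nPerGroup = 4L,
                      effectGenotype = c(1.0, -0.8, 0.5, 0, 0),
                      effectAge = c(0, 0.6, -0.5, 1.0, 0),
                      loadingMean = 1,
                      loadingSd = 0.2,
                      noiseSd = 0.8,
                      markerOverlap = NULL,
                      seed = 1L) {
    if (is.null(markerOverlap)) {
        markerOverlap <- list(
            Microglia = c(module = 1, fraction = 0.8, size = 40),
            Astrocyte = c(module = 2, fraction = 0.4, size = 40),
            Neuron = c(module = 3, fraction = 0.4, size = 40),
            Oligodendrocyte = c(module = 4, fraction = 0.4, size = 40))
        markerOverlap <- Filter(function(m) m[["module"]] <= nModules,
                                markerOverlap)
    }
    cfg <- list(nModules = as.integer(nModules),
                proteinsPerModule = as.integer(proteinsPerModule),
                nBackground = as.integer(nBackground),
                nHalfMissing = as.integer(nHalfMissing),
                nPerGroup = as.integer(nPerGroup),
                effectGenotype = rep_len(effectGenotype, nModules),
                effectAge = rep_len(effectAge, nModules),
                loadingMean = loadingMean,
                loadingSd = loadingSd,
                noiseSd = noiseSd,
                markerOverlap = markerOverlap,
                seed = as.integer(seed))
    stopifnot(cfg$nModules >= 1L, cfg$proteinsPerModule >= 2L,
              cfg$nBackground >= 0L, cfg$nHalfMissing >= 0L,
              cfg$nPerGroup >= 2L, cfg$noiseSd >= 0, cfg$loadingMean > 0)
    for (m in cfg$markerOverlap) {
        if (m[["module"]] > cfg$nModules)
            stop("markerOverlap refers to module ", m[["module"]],
                 " but only ", cfg$nModules, " are planted")
        stopifnot(m[["fraction"]] >= 0, m[["fraction"]] <= 1)
    }
    class(cfg) <- "SimConfig"
    cfg
}

#' Simulate a two-batch proteome with planted modules and ground truth
#'
#' Generative model: each module m has a latent eigenprofile over the 16
#' samples, e_m = beta_geno * I(KO) + beta_age * I(old) + N(0,1); a
#' protein p in module m is mu_p + loading_p * e_m + N(0, noiseSd^2);
#' background proteins are mu_p + N(0, noiseSd^2 + 1) pure noise (same
#' total variance as an average module member). Half-missing proteins
#' are ordinary module members masked to a single batch. Marker sets
#' mix module members and background per \code{markerOverlap}.
#'
#' @param config a \code{\link{simConfig}} list.
#' @return A list with components \code{proteome}
#'   (\linkS4class{ProteomeSet}), \code{truth} (class
#'   \code{"SyntheticTruth"}: \code{trueModule} named integer with 0 for
#'   background, \code{effectGenotype}/\code{effectAge} per module,
#'   \code{halfMissing} named logical, \code{eigenprofiles},
#'   \code{markerTruth}) and \code{markers}
#'   (\linkS4class{GeneSetCollection}).
#' @examples
#' sim <- simulateProteome(simConfig(nModules = 2, proteinsPerModule = 10,
#'                                   nBackground = 20, nHalfMissing = 4))
#' sim$proteome
#' @export
simulateProteome <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    npg <- config$nPerGroup
    meta <- expand.grid(replicate = seq_len(npg),
                        genotype = c("WT", "KO"),
                        age_group = c("young", "old"),
                        stringsAsFactors = FALSE)
    meta$batch <- paste0("batch_", meta$age_group)
    meta$sample_id <- paste(meta$genotype, meta$age_group, meta$replicate,
                            sep = ".")
    rownames(meta) <- meta$sample_id
    ns <- nrow(meta)

    isKO <- as.numeric(meta$genotype == "KO")
    isOld <- as.numeric(meta$age_group == "old")
    eig <- matrix(0, config$nModules, ns,
                  dimnames = list(NULL, meta$sample_id))
    for (m in seq_len(config$nModules))
        eig[m, ] <- config$effectGenotype[m] * isKO +
            config$effectAge[m] * isOld + stats::rnorm(ns)

    nMod <- config$nModules * config$proteinsPerModule
    nTot <- nMod + config$nBackground + config$nHalfMissing
    ids <- sprintf("prot%05d", seq_len(nTot))
    trueModule <- integer(nTot)
    names(trueModule) <- ids
    trueModule[seq_len(nMod)] <-
        rep(seq_len(config$nModules), each = config$proteinsPerModule)
    hmIdx <- if (config$nHalfMissing > 0)
        seq(nMod + config$nBackground + 1L, nTot) else integer(0)
    trueModule[hmIdx] <-
        rep_len(seq_len(config$nModules), config$nHalfMissing)

    mu <- stats::rnorm(nTot, mean = 22, sd = 1.5)
    loading <- stats::rnorm(nTot, config$loadingMean, config$loadingSd)
    values <- matrix(NA_real_, nTot, ns, dimnames = list(ids, meta$sample_id))
    for (i in seq_len(nTot)) {
        m <- trueModule[i]
        if (m > 0L) {
            values[i, ] <- mu[i] + loading[i] * eig[m, ] +
                stats::rnorm(ns, sd = config$noiseSd)
        } else {
            values[i, ] <- mu[i] +
                stats::rnorm(ns, sd = sqrt(config$noiseSd^2 + 1))
        }
    }

    pset <- ProteomeSet(values, meta)
    halfMissing <- stats::setNames(logical(nTot), ids)
    if (length(hmIdx)) {
        halfMissing[hmIdx] <- TRUE
        batches <- rep_len(c("batch_young", "batch_old"), length(hmIdx))
        for (b in unique(batches))
            pset <- injectHalfMissing(pset, ids[hmIdx][batches == b], b)
    }

    markerSets <- list()
    markerTruth <- list()
    bgIds <- ids[trueModule == 0L & !halfMissing]
    bgCursor <- 0L
    for (ct in names(config$markerOverlap)) {
        ov <- config$markerOverlap[[ct]]
        size <- if ("size" %in% names(ov)) as.integer(ov[["size"]])
                else config$proteinsPerModule
        nIn <- round(ov[["fraction"]] * size)
        modIds <- ids[trueModule == ov[["module"]] & !halfMissing]
        inMod <- modIds[seq_len(min(nIn, length(modIds)))]
        nOut <- size - length(inMod)
        filler <- bgIds[bgCursor + seq_len(min(nOut, length(bgIds) - bgCursor))]
        bgCursor <- bgCursor + length(filler)
        markerSets[[ct]] <- c(inMod, filler)
        markerTruth[[ct]] <- list(module = as.integer(ov[["module"]]),
                                  fraction = ov[["fraction"]],
                                  overlapIds = inMod)
    }

    truth <- structure(list(trueModule = trueModule,
                            effectGenotype = config$effectGenotype,
                            effectAge = config$effectAge,
                            halfMissing = halfMissing,
                            eigenprofiles = eig,
                            loadings = stats::setNames(loading, ids),
                            markerTruth = markerTruth),
                       class = "SyntheticTruth")
    list(proteome = pset, truth = truth,
         markers = GeneSetCollection(markerSets))
}

#' Mask a set of proteins outside one batch (batch-wise missingness)
#'
#' Reproduces the situation where a protein is quantified in one TMT
#' multiplex but not the other: every cell outside \code{batch} is set
#' unquantified, so with two equal batches the missing fraction of each
#' listed protein is exactly 0.5. Idempotent; an empty id list returns
#' the input unchanged.
#'
#' @param x a \linkS4class{ProteomeSet} with two equal-size batches.
#' @param proteins character vector of protein ids to restrict.
#' @param batch name of the batch the proteins remain quantified in.
#' @return The modified \linkS4class{ProteomeSet}.
#' @export
injectHalfMissing <- function(x, proteins, batch) {
    if (!length(proteins)) return(x)
    unknown <- setdiff(proteins, rownames(x))
    if (length(unknown))
        stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
    batches <- sampleInfo(x)$batch
    if (!batch %in% batches)
        stop("unknown batch: ", batch)
    tab <- table(batches)
    if (length(tab) != 2L || tab[1] != tab[2])
        stop("injectHalfMissing needs a two-equal-batch design")
    m <- quantMask(x)
    v <- log2Abundance(x)
    m[proteins, batches != batch] <- FALSE
    v[!m] <- NA_real_
    assays(x) <- list(log2 = v, mask = m)
    x
}

#' Write the simulated inputs as the standard on-disk artifacts
#'
#' Emits abundance.tsv, samples.csv, markers.gmt and truth.json so a
#' simulated data set can be re-analysed through the file-based
#' interface.
#'
#' @param sim result of \code{\link{simulateProteome}}.
#' @param outDir output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
writeSimulation <- function(sim, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    paths <- c(matrix = file.path(outDir, "abundance.tsv"),
               samples = file.path(outDir, "samples.csv"),
               markers = file.path(outDir, "markers.gmt"),
               truth = file.path(outDir, "truth.json"))
    writeAbundance(sim$proteome, paths["matrix"], paths["samples"])
    writeGMT(sim$markers, paths["markers"])
    tr <- sim$truth
    jsonlite::write_json(
        list(true_module = as.list(tr$trueModule),
             effect_genotype = tr$effectGenotype,
             effect_age = tr$effectAge,
             half_missing = names(tr$halfMissing)[tr$halfMissing]),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
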