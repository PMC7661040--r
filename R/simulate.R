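## Seed-reproducible synthetic two-species cohorts carrying the
## statistical structure every pipeline stage assumes: coverage-dependent
## missingness, linear and sigmoidal age trajectories, correlated CpG
## blocks conserved across species (with a chain file), cell-composition
## confounding, phenotype variables loading on a latent functional-decline
## factor, and a caloric-restriction effect that scales with time on diet.

#' Generator configuration
#'
#' Defaults emulate a rat cohort of 134 animals evenly spread over ages
#' 1-27 months (about five per monthly age group) and a mouse cohort of
#' 177 animals of which 20 underwent caloric restriction starting at 3.2
#' months of age, profiled at 20,000 CpGs (a desk-scale stand-in for a
#' multi-million-site RRBS matrix; the pipeline is dimension-agnostic).
#'
#' @param seed RNG seed; same seed, same bundle.
#' @param nRats,ratAges,nMice,nMiceCr cohort design.
#' @param nCpgs rat CpG count; `nMouseSpecific` extra mouse-only CpGs.
#' @param nAgeLinear,nAgeSigmoidal planted age-trend CpG counts.
#' @param nCellCpgs CpGs loading on cell composition.
#' @param moduleSpecs data.frame of planted co-methylation blocks: size,
#'   withinCor, ageWeight, frailtyWeight, densityProfile
#'   (dense/sparse/mixed/bimodal), regionTag.
#' @param conservedFraction fraction of rat CpGs planted as chain-mappable.
#' @param gapLoss approximate number of conserved CpGs placed in chain
#'   gaps (hence unmapped).
#' @param crossSpeciesSlope attenuation of age effects in the second
#'   species (0.5 halves every age slope).
#' @param nCellTypes simulated blood cell types.
#' @param coverageMean,coverageSize negative-binomial read coverage model.
#' @param missingExtra extra random record-dropout rate.
#' @param noiseSd Gaussian beta-scale noise s.d.
#' @param trajectoryNoiseSd extra per-site noise on the diffuse age-trend
#'   CpGs: individual aging trajectories are heterogeneous, so these CpGs
#'   correlate with age but, unlike the planted modules, not tightly with
#'   one another.
#' @param crShiftMonths constant CR displacement of effective age (months).
#' @param crDurationRate additional displacement per month on diet.
#' @param nPhenoFeatures,nFacsFeatures phenotype / FACS feature counts.
#' @return a named list (class `"generatorConfig"`).
#' @export
generatorConfig <- function(seed = 1L, nRats = 134L, ratAges = 1:27,
                            nMice = 177L, nMiceCr = 20L, nCpgs = 20000L,
                            nMouseSpecific = round(0.2 * nCpgs),
                            nAgeLinear = round(0.05 * nCpgs),
                            nAgeSigmoidal = round(0.025 * nCpgs),
                            nCellCpgs = round(0.05 * nCpgs),
                            moduleSpecs = NULL, conservedFraction = 0.2,
                            gapLoss = round(0.01875 * nCpgs),
                            crossSpeciesSlope = 0.5,
                            nCellTypes = 5L, coverageMean = 30,
                            coverageSize = 6, missingExtra = 0.02,
                            noiseSd = 0.05, trajectoryNoiseSd = 0.11,
                            crShiftMonths = -1.2,
                            crDurationRate = -0.1, nPhenoFeatures = 10L,
                            nFacsFeatures = 39L) {
    if (is.null(moduleSpecs))
        moduleSpecs <- data.frame(
            size = c(64L, 47L, 44L, 38L),
            withinCor = 0.95,
            ageWeight = c(0.35, 0.00, 0.60, 0.70),
            frailtyWeight = c(0.30, 0.00, 0.00, 0.30),
            densityProfile = c("dense", "mixed", "sparse", "bimodal"),
            regionTag = c("H3K9me3-like", "none", "none", "H3K27me3-like"),
            stringsAsFactors = FALSE)
    if (is.null(moduleSpecs$withinCor)) moduleSpecs$withinCor <- 0.95
    cfg <- as.list(environment())
    nRoles <- sum(moduleSpecs$size) + nAgeLinear + nAgeSigmoidal + nCellCpgs
    if (nRoles > nCpgs)
        stop("module/signal CpG counts exceed nCpgs")
    if (round(conservedFraction * nCpgs) < sum(moduleSpecs$size) + gapLoss)
        stop("conserved fraction too small for the planted modules and gaps")
    structure(cfg, class = "generatorConfig")
}

## Clustered site layout: cluster anchors ~40 kb apart, cluster sizes 1-6
## with tight (10-25 bp) internal spacing, so local CpG density separates
## "dense" (cluster size >= 4) from "sparse" (singleton) pools.
.layoutSites <- function(nCpgs, nChroms = 4L, interClusterBp = 40000) {
    chrom <- character(0); pos <- integer(0); clusterId <- integer(0)
    perChrom <- diff(round(seq(0, nCpgs, length.out = nChroms + 1L)))
    cid <- 0L
    for (ci in seq_len(nChroms)) {
        need <- perChrom[ci]
        p <- 50000L
        cp <- integer(0); cc <- integer(0)
        while (length(cp) < need) {
            cid <- cid + 1L
            s <- sample(c(1L, 1L, 2L, 3L, 4L, 5L, 6L), 1L)
            s <- min(s, need - length(cp))
            within <- cumsum(c(0L, sample(10:25, max(s - 1L, 0L),
                                          replace = TRUE)))
            cp <- c(cp, p + within)
            cc <- c(cc, rep(cid, s))
            p <- p + max(within) + 5000L +
                as.integer(stats::rexp(1L, 1 / interClusterBp))
        }
        chrom <- c(chrom, rep(paste0("chr", ci), need))
        pos <- c(pos, cp)
        clusterId <- c(clusterId, cc)
    }
    clSize <- ave(clusterId, clusterId, FUN = length)
    data.frame(chrom = chrom, pos = pos, cluster = clusterId,
               dense = clSize >= 4L, sparse = clSize == 1L,
               stringsAsFactors = FALSE)
}

.pickByProfile <- function(profile, n, pools, used) {
    avail <- function(v) setdiff(v, used)
    pick <- switch(profile,
        dense = avail(pools$dense),
        sparse = avail(pools$sparse),
        bimodal = c(sample(avail(pools$dense), ceiling(n / 2)),
                    sample(avail(pools$sparse), floor(n / 2))),
        avail(pools$all))
    if (profile %in% c("dense", "sparse", "mixed"))
        pick <- sample(pick, n)
    if (length(pick) < n)
        stop("not enough ", profile, " sites for a planted module")
    pick[seq_len(n)]
}

## Build one chain per rat chromosome mapping the conserved CpGs to the
## mouse assembly; conserved sites inside dt-gaps stay unmapped. The last
## chromosome's chain has a minus-strand target.
.buildChain <- function(layout, conservedIdx, gapLoss, protectedIdx) {
    chroms <- unique(layout$chrom)
    lines <- character(0)
    lostIdx <- integer(0)
    perChromLoss <- round(gapLoss * table(factor(layout$chrom[conservedIdx],
                                                 chroms)) /
                          length(conservedIdx))
    for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        idx <- conservedIdx[layout$chrom[conservedIdx] == ch]
        idx <- idx[order(layout$pos[idx])]
        if (!length(idx)) next
        ## short segments of consecutive conserved sites; some become gap
        ## losses (short, so enough segments are free of protected sites)
        segLen <- pmax(4L, stats::rpois(length(idx), 9L))
        segId <- rep(seq_along(segLen), segLen)[seq_along(idx)]
        nSeg <- max(segId)
        lossTarget <- perChromLoss[ci]
        lost <- logical(nSeg)
        segList <- split(idx, segId)
        segSizes <- lengths(segList)
        ## planted module/age-signal CpGs are never lost to chain gaps
        eligible <- !vapply(segList, function(s) any(s %in% protectedIdx),
                            TRUE)
        lostSum <- 0L
        for (s in sample(seq_len(nSeg))) {
            if (lostSum >= lossTarget) break
            if (!eligible[s]) next
            if (lostSum + segSizes[s] > lossTarget + 12L) next
            lost[s] <- TRUE
            lostSum <- lostSum + segSizes[s]
        }
        if (all(lost)) lost[1L] <- FALSE
        minus <- ci == length(chroms)
        segIdxList <- split(idx, segId)
        srcS <- srcE <- tgtLen <- numeric(0)
        keptSegs <- which(!lost)
        for (s in keptSegs) {
            p <- layout$pos[segIdxList[[s]]]
            srcS <- c(srcS, min(p) - 10L)   # 0-based start
            srcE <- c(srcE, max(p) + 10L)   # half-open end (pos is 1-based)
            tgtLen <- c(tgtLen, max(p) + 10L - (min(p) - 10L))
        }
        for (s in which(lost)) lostIdx <- c(lostIdx, segIdxList[[s]])
        o <- order(srcS)
        srcS <- srcS[o]; srcE <- srcE[o]; tgtLen <- tgtLen[o]
        sizes <- srcE - srcS
        dt <- c(diff(srcS) - sizes[-length(sizes)], 0)
        dq <- pmax(0, round(dt * stats::runif(length(dt), 0.6, 0.95)))
        tgtS <- cumsum(c(20000, sizes[-length(sizes)] +
                                dq[-length(dq)]))
        tgtE <- tgtS + sizes
        qEndLocal <- tgtE[length(tgtE)]
        qSize <- qEndLocal + 30000
        tName <- ch; qName <- paste0("chr", ci)
        tSize <- max(layout$pos[layout$chrom == ch]) + 50000
        hdr <- sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                       1000L - ci, tName, as.integer(tSize),
                       as.integer(srcS[1L]), as.integer(srcE[length(srcE)]),
                       qName, as.integer(qSize), if (minus) "-" else "+",
                       as.integer(tgtS[1L]), as.integer(qEndLocal), ci)
        body <- character(length(sizes))
        for (k in seq_along(sizes)) {
            body[k] <- if (k < length(sizes))
                sprintf("%d %d %d", as.integer(sizes[k]),
                        as.integer(dt[k]), as.integer(dq[k]))
            else sprintf("%d", as.integer(sizes[k]))
        }
        lines <- c(lines, hdr, body, "")
    }
    list(lines = lines, lostIdx = sort(lostIdx))
}

.softmax <- function(m) {
    e <- exp(m - apply(m, 1L, max))
    e / rowSums(e)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Synthesize a sites x samples true-beta matrix for one species.
.synthBeta <- function(roles, base, amp, dir, mid, scl, cellType, cellLoad,
                       moduleOf, moduleLambda, cfg, ages, effAges, props,
                       frailResid, slopeFactor, specs) {
    n <- length(ages)
    p <- length(roles)
    zAge <- as.numeric(scale(effAges))
    B <- matrix(stats::rnorm(p * n, 0, cfg$noiseSd), p, n) + base
    ageTermL <- outer(amp * dir * slopeFactor, (effAges - 14) / 26)
    lin <- roles == "age_linear"
    B[lin, ] <- B[lin, ] + ageTermL[lin, , drop = FALSE]
    sig <- which(roles == "age_sigmoidal")
    if (length(sig)) {
        for (i in sig)
            B[i, ] <- B[i, ] + dir[i] * amp[i] * slopeFactor *
                (stats::plogis((effAges - mid[i]) / scl[i]) - 0.5)
    }
    trend <- lin | roles == "age_sigmoidal"
    if (any(trend))    # heterogeneous trajectories: age-linked, not co-methylated
        B[trend, ] <- B[trend, ] +
            matrix(stats::rnorm(sum(trend) * n, 0, cfg$trajectoryNoiseSd),
                   sum(trend), n)
    cel <- which(roles == "cell")
    if (length(cel)) {
        pc <- sweep(props, 2L, colMeans(props))
        for (i in cel)
            B[i, ] <- B[i, ] + cellLoad[i] * pc[, cellType[i]]
    }
    for (m in seq_len(nrow(specs))) {
        mi <- which(moduleOf == m)
        if (!length(mi)) next
        wA <- specs$ageWeight[m] * slopeFactor
        wF <- if (is.null(frailResid)) 0 else specs$frailtyWeight[m]
        wN <- sqrt(max(1 - wA^2 - wF^2, 0.05))
        L <- wA * zAge + wN * stats::rnorm(n)
        if (wF > 0) L <- L + wF * frailResid
        B[mi, ] <- B[mi, ] + outer(moduleLambda[mi], L)
    }
    .clamp01(B)
}

## Observe a true-beta matrix through the coverage model; returns per
## sample a MethylationCallSet (records with coverage > 0 that survive
## the extra dropout).
.observe <- function(Btrue, sites, sampleIds, cfg) {
    p <- nrow(Btrue); n <- ncol(Btrue)
    lapply(seq_len(n), function(j) {
        cov <- stats::rnbinom(p, size = cfg$coverageSize,
                              mu = cfg$coverageMean)
        meth <- stats::rbinom(p, cov, Btrue[, j])
        keep <- cov > 0 & stats::runif(p) >= cfg$missingExtra
        gr <- sites[keep]
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            beta = meth[keep] / cov[keep], coverage = cov[keep])
        MethylationCallSet(sampleIds[j], gr)
    })
}

#' Generate a synthetic two-species cohort bundle
#'
#' Per-CpG beta is a clamped sum of a baseline, an age trend (linear or
#' logistic in effective age), a co-methylation module latent factor, a
#' cell-composition term, and Gaussian noise; caloric restriction shifts
#' a mouse's effective age by `crShiftMonths + crDurationRate * months on
#' diet`. Observed calls add binomial sampling noise at a
#' negative-binomial read coverage, and entries are absent when coverage
#' is zero or dropped by `missingExtra` (entries at coverage <= 10 are
#' masked downstream by [assembleMatrix()]). Conserved CpGs map to the
#' second assembly through a generated UCSC chain file (with gaps and one
#' minus-strand chain); age slopes in the second species are attenuated
#' by `crossSpeciesSlope`. Rat phenotype features load on a latent
#' frailty factor whose individual (age-independent) part also drives two
#' module latents; FACS features derive from simulated cell proportions
#' drifting with age.
#'
#' @param cfg a [generatorConfig()].
#' @return a bundle list: `ratCalls`/`mouseCalls` (lists of
#'   \linkS4class{MethylationCallSet}), `ratBetaTrue`/`mouseBetaTrue`
#'   (latent matrices), `ratSites`/`mouseSites` (GRanges), `samples`
#'   (combined metadata), `pheno`, `facs`, `chain`
#'   (\linkS4class{ChainAlignment}), `chainLines`, `mapped` (src/tgt
#'   pairing of conserved CpGs), `geneModels`, `regionSets`,
#'   `fastaExcerpt` (small synthetic contigs), and `manifest` (planted
#'   truth).
#' @export
simulateCohort <- function(cfg = generatorConfig()) {
    .withSeed(cfg$seed, {
        specs <- cfg$moduleSpecs
        layout <- .layoutSites(cfg$nCpgs)
        ratSites <- GenomicRanges::GRanges(
            layout$chrom, IRanges::IRanges(layout$pos, width = 1L))
        ratIds <- siteIdOf(ratSites)
        names(ratSites) <- ratIds

        ## ---- roles -------------------------------------------------------
        pools <- list(dense = which(layout$dense),
                      sparse = which(layout$sparse),
                      all = seq_len(cfg$nCpgs))
        roles <- rep("null", cfg$nCpgs)
        moduleOf <- rep(NA_integer_, cfg$nCpgs)
        used <- integer(0)
        for (m in seq_len(nrow(specs))) {
            pick <- .pickByProfile(specs$densityProfile[m], specs$size[m],
                                   pools, used)
            roles[pick] <- "module"
            moduleOf[pick] <- m
            used <- c(used, pick)
        }
        rest <- setdiff(seq_len(cfg$nCpgs), used)
        pick <- sample(rest, cfg$nAgeLinear + cfg$nAgeSigmoidal + cfg$nCellCpgs)
        roles[pick[seq_len(cfg$nAgeLinear)]] <- "age_linear"
        roles[pick[cfg$nAgeLinear + seq_len(cfg$nAgeSigmoidal)]] <- "age_sigmoidal"
        roles[pick[cfg$nAgeLinear + cfg$nAgeSigmoidal +
                   seq_len(cfg$nCellCpgs)]] <- "cell"

        ## ---- conserved subset & chain ------------------------------------
        conservedN <- round(cfg$conservedFraction * cfg$nCpgs)
        mustKeep <- which(roles == "module")
        sigIdx <- c(sample(which(roles == "age_linear"),
                           min(450L, round(0.45 * cfg$nAgeLinear))),
                    sample(which(roles == "age_sigmoidal"),
                           min(200L, round(0.4 * cfg$nAgeSigmoidal))))
        nullPool <- which(roles == "null")
        fill <- sample(nullPool, conservedN - length(mustKeep) - length(sigIdx))
        conservedIdx <- sort(c(mustKeep, sigIdx, fill))
        chainInfo <- .buildChain(layout, conservedIdx, cfg$gapLoss,
                                 protectedIdx = c(mustKeep, sigIdx))
        chainPath <- tempfile(fileext = ".chain")
        writeLines(chainInfo$lines, chainPath)
        chain <- readChain(chainPath)
        unlink(chainPath)
        mappedAll <- liftoverSites(chain, ratSites[conservedIdx])
        mapped <- mappedAll[!is.na(mappedAll$tgt), ]
        rownames(mapped) <- NULL

        ## ---- cohorts -----------------------------------------------------
        ratAge <- rep(cfg$ratAges, length.out = cfg$nRats)
        ratId <- sprintf("R%03d", seq_len(cfg$nRats))
        crDur <- c(stats::runif(cfg$nMiceCr, 6.5, 23), rep(0, cfg$nMice - cfg$nMiceCr))
        mouseAge <- c(3.2 + crDur[seq_len(cfg$nMiceCr)],
                      stats::runif(cfg$nMice - cfg$nMiceCr, 1, 34))
        mouseDiet <- c(rep("CR", cfg$nMiceCr), rep("AL", cfg$nMice - cfg$nMiceCr))
        mouseId <- sprintf("M%03d", seq_len(cfg$nMice))
        mouseEff <- mouseAge + (mouseDiet == "CR") *
            (cfg$crShiftMonths + cfg$crDurationRate * crDur)
        samples <- data.frame(
            sample_id = c(ratId, mouseId),
            species = c(rep("rat", cfg$nRats), rep("mouse", cfg$nMice)),
            age_months = c(ratAge, mouseAge),
            diet = c(rep("AL", cfg$nRats), mouseDiet),
            cr_duration_months = c(rep(0, cfg$nRats), crDur),
            tissue = "blood", split = "none", stringsAsFactors = FALSE)
        rownames(samples) <- samples$sample_id

        ## ---- latent structure shared across species ----------------------
        base <- stats::runif(cfg$nCpgs, 0.25, 0.75)
        amp <- stats::runif(cfg$nCpgs, 0.15, 0.4)
        dir <- sample(c(-1, 1), cfg$nCpgs, replace = TRUE)
        mid <- stats::runif(cfg$nCpgs, 6, 20)
        scl <- stats::runif(cfg$nCpgs, 2, 5)
        cellType <- sample(cfg$nCellTypes, cfg$nCpgs, replace = TRUE)
        cellLoad <- stats::runif(cfg$nCpgs, 0.2, 0.6)
        moduleLambda <- rep(0, cfg$nCpgs)
        for (m in seq_len(nrow(specs))) {
            wc <- specs$withinCor[m]
            moduleLambda[which(moduleOf == m)] <-
                cfg$noiseSd * sqrt(wc / (1 - wc))
        }

        ## cell proportions drifting with age
        cellDrift <- stats::runif(cfg$nCellTypes, -0.8, 0.8)
        propsOf <- function(ages) .softmax(
            outer(rep(1, length(ages)), stats::rnorm(cfg$nCellTypes, 0, 0.2)) +
            outer((ages - 14) / 13, cellDrift) +
            matrix(stats::rnorm(length(ages) * cfg$nCellTypes, 0, 0.15),
                   length(ages)))
        ratProps <- propsOf(ratAge)
        mouseProps <- propsOf(mouseAge)

        ## frailty: age-driven decline plus individual part (rats only)
        frail <- 0.06 * (ratAge - 14) + stats::rnorm(cfg$nRats, 0, 0.6)
        frailResid <- as.numeric(scale(frail - 0.06 * (ratAge - 14)))

        ratBeta <- .synthBeta(roles, base, amp, dir, mid, scl, cellType,
                              cellLoad, moduleOf, moduleLambda, cfg,
                              ratAge, ratAge, ratProps, frailResid,
                              slopeFactor = 1, specs = specs)
        dimnames(ratBeta) <- list(ratIds, ratId)

        ## mouse matrix: mapped conserved sites inherit rat roles; extra
        ## mouse-specific sites are mostly null with some age signal
        mouseConsIdx <- match(mapped$src, ratIds)
        nmc <- length(mouseConsIdx)
        nms <- cfg$nMouseSpecific
        nmsSig <- min(200L, round(0.2 * nms))
        msRoles <- c(roles[mouseConsIdx],
                     sample(c(rep("age_linear", nmsSig),
                              rep("null", nms - nmsSig))))
        msModuleOf <- c(moduleOf[mouseConsIdx], rep(NA_integer_, nms))
        msLambda <- c(moduleLambda[mouseConsIdx], rep(0, nms))
        msBase <- c(base[mouseConsIdx], stats::runif(nms, 0.25, 0.75))
        msAmp <- c(amp[mouseConsIdx], stats::runif(nms, 0.15, 0.4))
        msDir <- c(dir[mouseConsIdx], sample(c(-1, 1), nms, replace = TRUE))
        msMid <- c(mid[mouseConsIdx], stats::runif(nms, 6, 20))
        msScl <- c(scl[mouseConsIdx], stats::runif(nms, 2, 5))
        msCellType <- c(cellType[mouseConsIdx],
                        sample(cfg$nCellTypes, nms, replace = TRUE))
        msCellLoad <- c(cellLoad[mouseConsIdx], stats::runif(nms, 0.2, 0.6))
        ## mouse-specific positions: beyond the mapped range, well spaced
        consTgt <- .parseSiteIds(mapped$tgt)
        msChrom <- sample(paste0("chr", 1:4), nms, replace = TRUE)
        maxTgt <- max(GenomicRanges::start(consTgt)) + 1e6
        msPos <- maxTgt + seq_len(nms) * 2000L
        mouseSites <- suppressWarnings(c(consTgt, GenomicRanges::GRanges(
            msChrom, IRanges::IRanges(msPos, width = 1L))))
        mo <- .siteOrder(mouseSites)
        mouseIds <- siteIdOf(mouseSites)
        mouseBeta <- .synthBeta(msRoles, msBase, msAmp, msDir, msMid, msScl,
                                msCellType, msCellLoad, msModuleOf, msLambda,
                                cfg, mouseAge, mouseEff, mouseProps,
                                frailResid = NULL,
                                slopeFactor = cfg$crossSpeciesSlope,
                                specs = specs)
        dimnames(mouseBeta) <- list(mouseIds, mouseId)
        mouseSites <- mouseSites[mo]
        mouseBeta <- mouseBeta[mo, , drop = FALSE]
        msRolesSorted <- msRoles[mo]
        msModuleSorted <- msModuleOf[mo]
        names(mouseSites) <- rownames(mouseBeta)

        ## ---- observation through the coverage model ----------------------
        ratCalls <- .observe(ratBeta, ratSites, ratId, cfg)
        mouseCalls <- .observe(mouseBeta, mouseSites, mouseId, cfg)

        ## ---- phenotype & FACS features (rats) ----------------------------
        zf <- as.numeric(scale(frail))
        phLoad <- stats::runif(cfg$nPhenoFeatures, 0.5, 0.95)
        pheno <- sapply(seq_len(cfg$nPhenoFeatures), function(j)
            phLoad[j] * zf + stats::rnorm(cfg$nRats, 0, 0.6))
        colnames(pheno) <- c(paste0("openfield_", seq_len(cfg$nPhenoFeatures - 2L)),
                             "rotarod_max", "rotarod_mean")
        rownames(pheno) <- ratId
        fcType <- sample(cfg$nCellTypes, cfg$nFacsFeatures, replace = TRUE)
        fcW <- stats::runif(cfg$nFacsFeatures, 0.6, 1)
        facs <- sapply(seq_len(cfg$nFacsFeatures), function(j)
            fcW[j] * as.numeric(scale(ratProps[, fcType[j]])) +
                stats::rnorm(cfg$nRats, 0, 0.3))
        colnames(facs) <- paste0("facs_", seq_len(cfg$nFacsFeatures))
        rownames(facs) <- ratId

        ## ---- gene models, region sets, FASTA excerpt ---------------------
        geneModels <- .plantGenes(layout, moduleOf, specs)
        regionSets <- .plantRegions(layout, moduleOf, roles, specs)
        fastaExcerpt <- .fastaExcerpt()

        maskP <- stats::pnbinom(10, size = cfg$coverageSize,
                                mu = cfg$coverageMean)
        maskP <- maskP + (1 - maskP) * cfg$missingExtra
        manifest <- list(
            config = cfg[setdiff(names(cfg), "moduleSpecs")],
            moduleSpecs = specs,
            roles = data.frame(site = ratIds, role = roles,
                               module = moduleOf, stringsAsFactors = FALSE),
            mouseRoles = data.frame(site = rownames(mouseBeta),
                                    role = msRolesSorted,
                                    module = msModuleSorted,
                                    stringsAsFactors = FALSE),
            conservedIds = ratIds[conservedIdx],
            gapLostIds = ratIds[chainInfo$lostIdx],
            mappedCount = nrow(mapped),
            analyticMaskProb = maskP,
            planted = list(crShiftMonths = cfg$crShiftMonths,
                           crDurationRate = cfg$crDurationRate,
                           crossSpeciesSlope = cfg$crossSpeciesSlope))

        list(ratCalls = ratCalls, mouseCalls = mouseCalls,
             ratBetaTrue = ratBeta, mouseBetaTrue = mouseBeta,
             ratSites = ratSites, mouseSites = mouseSites,
             samples = samples, pheno = as.data.frame(pheno),
             facs = as.data.frame(facs), chain = chain,
             chainLines = chainInfo$lines, mapped = mapped,
             geneModels = geneModels, regionSets = regionSets,
             fastaExcerpt = fastaExcerpt, manifest = manifest)
    })
}

## Genes placed away (>10 kb) from module CpGs so the planted modules
## stay intergenic, mirroring the heterochromatin-like localisation.
.plantGenes <- function(layout, moduleOf, specs, nGenes = 120L) {
    modPos <- split(layout$pos[!is.na(moduleOf)],
                    layout$chrom[!is.na(moduleOf)])
    chroms <- unique(layout$chrom)
    rows <- list()
    g <- 0L
    for (ch in chroms) {
        span <- range(layout$pos[layout$chrom == ch])
        tries <- 0L
        while (g < nGenes * match(ch, chroms) / length(chroms) &&
               tries < 500L) {
            tries <- tries + 1L
            st <- round(stats::runif(1, span[1], span[2] - 60000))
            len <- round(stats::runif(1, 5000, 50000))
            mp <- modPos[[ch]]
            if (!is.null(mp) && any(mp > st - 11000 & mp < st + len + 11000))
                next
            g <- g + 1L
            rows[[g]] <- data.frame(chrom = ch, start = st, end = st + len,
                                    strand = sample(c("+", "-"), 1L),
                                    gene_id = sprintf("gene%03d", g))
        }
    }
    gdf <- do.call(rbind, rows)
    genes <- GenomicRanges::GRanges(
        gdf$chrom, IRanges::IRanges(gdf$start, gdf$end),
        strand = gdf$strand, gene_id = gdf$gene_id)
    exons <- suppressWarnings(do.call(c, lapply(seq_along(genes), function(i) {
        nEx <- sample(2:4, 1L)
        len <- GenomicRanges::width(genes)[i]
        st <- sort(sample(seq(0, len - 400), nEx))
        GenomicRanges::GRanges(
            gdf$chrom[i],
            IRanges::IRanges(gdf$start[i] + st,
                             width = pmin(300L, len - st)),
            strand = gdf$strand[i], gene_id = gdf$gene_id[i])
    })))
    list(genes = genes, exons = exons)
}

## Region sets covering the tagged modules plus a background fraction of
## untagged CpGs, so enrichment recovers fold > 1 for the matched set.
.plantRegions <- function(layout, moduleOf, roles, specs, bgFraction = 0.13) {
    mk <- function(idx) {
        gr <- GenomicRanges::GRanges(
            layout$chrom[idx],
            IRanges::IRanges(pmax(1L, layout$pos[idx] - 100L),
                             layout$pos[idx] + 100L))
        GenomicRanges::sort(GenomicRanges::reduce(gr))
    }
    sets <- list()
    for (m in seq_len(nrow(specs))) {
        tag <- specs$regionTag[m]
        if (tag == "none") next
        others <- which(is.na(moduleOf))
        bg <- sample(others, round(bgFraction * length(others) / 4))
        sets[[tag]] <- mk(c(which(moduleOf == m), bg))
    }
    ## a neutral set with no module preference
    sets[["neutral-like"]] <- mk(sample(which(is.na(moduleOf)), 400L))
    sets
}

.fastaExcerpt <- function(len = 12000L) {
    mkseq <- function()
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    ss <- Biostrings::DNAStringSet(c(excerpt1 = mkseq(), excerpt2 = mkseq()))
    ss
}

#' Write a cohort bundle to disk
#'
#' Emits cov-dialect call TSVs per sample (`calls/<id>.cov.tsv`), the
#' sample/phenotype/FACS tables, the UCSC chain, gene models (GFF3),
#' region-set BEDs, the synthetic FASTA excerpt and a JSON truth
#' manifest. All files re-parse through the package's own readers.
#'
#' @param bundle output of [simulateCohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
    dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "regions"), showWarnings = FALSE)
    for (cs in c(bundle$ratCalls, bundle$mouseCalls)) {
        gr <- cs@calls
        mc <- S4Vectors::mcols(gr)
        meth <- round(mc$beta * mc$coverage)
        dt <- data.table::data.table(
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr),
            end = GenomicRanges::start(gr),
            pct = 100 * mc$beta, meth = meth, unmeth = mc$coverage - meth)
        data.table::fwrite(dt, file.path(dir, "calls",
                                         paste0(cs@sampleId, ".cov.tsv")),
                           sep = "\t", col.names = FALSE)
    }
    data.table::fwrite(bundle$samples, file.path(dir, "samples.tsv"),
                       sep = "\t")
    data.table::fwrite(cbind(sample_id = rownames(bundle$pheno), bundle$pheno),
                       file.path(dir, "pheno.tsv"), sep = "\t")
    data.table::fwrite(cbind(sample_id = rownames(bundle$facs), bundle$facs),
                       file.path(dir, "facs.tsv"), sep = "\t")
    writeLines(bundle$chainLines, file.path(dir, "synthetic.chain"))
    .writeGff3(bundle$geneModels, file.path(dir, "genes.gff3"))
    for (nm in names(bundle$regionSets)) {
        gr <- bundle$regionSets[[nm]]
        dt <- data.table::data.table(
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,   # BED is 0-based
            end = GenomicRanges::end(gr))
        data.table::fwrite(dt, file.path(dir, "regions", paste0(nm, ".bed")),
                           sep = "\t", col.names = FALSE)
    }
    Biostrings::writeXStringSet(bundle$fastaExcerpt,
                                file.path(dir, "genome_excerpt_synthetic.fa"))
    mf <- bundle$manifest
    jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(dir)
}

.writeGff3 <- function(geneModels, path) {
    fmt <- function(gr, type, idcol) {
        sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(GenomicRanges::seqnames(gr)), type,
                GenomicRanges::start(gr), GenomicRanges::end(gr),
                as.character(GenomicRanges::strand(gr)), idcol)
    }
    g <- geneModels$genes
    e <- geneModels$exons
    lines <- c("##gff-version 3",
               fmt(g, "gene", paste0("ID=", g$gene_id)),
               fmt(e, "exon", paste0("ID=", e$gene_id, ".ex",
                                     seq_along(e), ";Parent=", e$gene_id)))
    writeLines(lines, path)
}

#' Compare recovered quantities against the planted truth
#'
#' @param bundle a [simulateCohort()] bundle (its manifest is the truth).
#' @param results named list; recognised elements: `clockBicor` (test-set
#'   age correlation), `assignment` (\linkS4class{ModuleAssignment} over
#'   conserved source sites), `crCoefMonths` and `crCoefSe` (fitted CR
#'   main effect), `enrichment` (data.frame from [regionEnrichment()]).
#' @param bicorFloor,ariFloor pass thresholds for the clock correlation
#'   and the module adjusted Rand index.
#' @return data.frame with one row per check: check, value, target, pass.
#' @export
truthCheck <- function(bundle, results, bicorFloor = 0.9, ariFloor = 0.9) {
    mf <- bundle$manifest
    rows <- list()
    if (!is.null(results$clockBicor))
        rows$clock <- data.frame(check = "clock_age_bicor",
                                 value = results$clockBicor,
                                 target = bicorFloor,
                                 pass = results$clockBicor >= bicorFloor)
    if (!is.null(results$assignment)) {
        lab <- moduleLabels(results$assignment)
        truth <- mf$roles$module[match(names(lab), mf$roles$site)]
        truth[is.na(truth)] <- 0L
        ari <- adjustedRand(lab, truth)
        rows$ari <- data.frame(check = "module_adjusted_rand", value = ari,
                               target = ariFloor, pass = ari >= ariFloor)
    }
    if (!is.null(results$crCoefMonths)) {
        tgt <- mf$planted$crShiftMonths
        se <- if (is.null(results$crCoefSe)) NA_real_ else results$crCoefSe
        ok <- if (is.na(se)) results$crCoefMonths < 0
              else abs(results$crCoefMonths - tgt) <= 2 * se
        rows$cr <- data.frame(check = "cr_effect_months",
                              value = results$crCoefMonths, target = tgt,
                              pass = ok)
    }
    if (!is.null(results$enrichment)) {
        tagged <- setdiff(unique(mf$moduleSpecs$regionTag), "none")
        for (tg in intersect(tagged, results$enrichment$set)) {
            f <- results$enrichment$fold[results$enrichment$set == tg]
            rows[[tg]] <- data.frame(check = paste0("enrichment_", tg),
                                     value = f, target = 1,
                                     pass = f > 1)
        }
    }
    if (!length(rows)) stop("no recognised results supplied")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
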