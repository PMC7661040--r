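# Small in-code fixtures shared across test files.

# sites x samples BetaMatrix from a plain matrix and positions
toyBetaMatrix <- function(beta, chrom = rep("chr1", nrow(beta)),
                          pos = seq_len(nrow(beta)) * 1000L,
                          sampleData = NULL) {
    colnames(beta) <- colnames(beta) %||% paste0("S", seq_len(ncol(beta)))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    BetaMatrix(beta, gr, sampleData = sampleData)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeCovFixture <- function(path, rows) {
    # rows: data.frame chrom, pos, pct, meth, unmeth
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d", rows$chrom, rows$pos,
                       rows$pos, format(rows$pct), rows$meth, rows$unmeth),
               path)
    path
}

# a simple one-chain fixture: one chromosome, three blocks separated by
# two gaps, constant +10 target offset in the first block, then shifts
writeGappyChain <- function(path) {
    writeLines(c(
        # chain: src chr1 0-based [100,400) in three ungapped blocks
        #   block1 src [100,200) -> tgt [110,210)   (+10)
        #   gap: dt=50 dq=20
        #   block2 src [250,300) -> tgt [230,280)   (-20)
        #   gap: dt=30 dq=60
        #   block3 src [330,400) -> tgt [340,410)   (+10)
        "chain 900 chr1 1000 + 100 400 chr1 1200 + 110 410 1",
        "100 50 20",
        "50 30 60",
        "70",
        ""), path)
    path
}

writeMinusChain <- function(path) {
    # one block src chr1 [100,200) -> target chr2 minus strand,
    # strand-local [30,130), qSize 500: plus-strand interval [370,470)
    writeLines(c(
        "chain 800 chr1 1000 + 100 200 chr2 500 - 30 130 7",
        "100",
        ""), path)
    path
}

writeIdentityChain <- function(path, chrom = "chr1", size = 1000L) {
    writeLines(c(sprintf("chain 1000 %s %d + 0 %d %s %d + 0 %d 1",
                         chrom, size, size, chrom, size, size),
                 as.character(size), ""), path)
    path
}

# correlated block design: nBlocks blocks of blockSize CpGs each driven
# by its own latent, plus nNoise independent CpGs
plantedBlockMatrix <- function(nBlocks = 2, blockSize = 30, nNoise = 40,
                               nSamples = 40, withinCor = 0.9, seed = 7) {
    set.seed(seed)
    lambda <- sqrt(withinCor)
    eps <- sqrt(1 - withinCor)
    rows <- list()
    truth <- integer(0)
    for (bkt in seq_len(nBlocks)) {
        L <- rnorm(nSamples)
        for (i in seq_len(blockSize))
            rows[[length(rows) + 1L]] <- lambda * L + eps * rnorm(nSamples)
        truth <- c(truth, rep(bkt, blockSize))
    }
    for (i in seq_len(nNoise)) {
        rows[[length(rows) + 1L]] <- rnorm(nSamples)
        truth <- c(truth, 0L)
    }
    B <- do.call(rbind, rows)
    # shift/scale into [0,1] beta-like range
    B <- 0.5 + 0.12 * B / max(abs(B)) * 4
    B <- pmin(pmax(B, 0), 1)
    rownames(B) <- paste0("chr1:", seq_len(nrow(B)) * 100L)
    colnames(B) <- paste0("S", seq_len(nSamples))
    list(beta = B, truth = truth)
}

# tiny mouse-like cohort for CR recovery tests: small CpG panel with a
# clean linear age axis (age-neutral modules, little trajectory noise),
# no cross-species attenuation, selectable CR planting
tinyCrConfig <- function(seed, crShiftMonths, crDurationRate = 0) {
    generatorConfig(
        seed = seed, nRats = 30L, nMice = 120L, nMiceCr = 20L,
        nCpgs = 600L, nMouseSpecific = 100L, nAgeLinear = 250L,
        nAgeSigmoidal = 0L, nCellCpgs = 50L, trajectoryNoiseSd = 0.05,
        moduleSpecs = data.frame(size = c(25L, 25L), withinCor = 0.9,
                                 ageWeight = 0, frailtyWeight = 0,
                                 densityProfile = "mixed",
                                 regionTag = c("H3K9me3-like", "none"),
                                 stringsAsFactors = FALSE),
        conservedFraction = 0.5, gapLoss = 20L,
        crossSpeciesSlope = 1, noiseSd = 0.05,
        crShiftMonths = crShiftMonths, crDurationRate = crDurationRate)
}

# fit a PC1 clock on the AL mice of a tiny bundle (latent matrices) and
# return the CR main-effect fit
fitTinyCrEffect <- function(bundle) {
    mouse <- samplesOf(bundle, "mouse")
    B <- bundle$mouseBetaTrue
    al <- mouse$sample_id[mouse$diet == "AL"]
    pca <- fitPCA(B[, al], nComponents = 1L)
    clk <- fitPCClock(pca, B[, al], mouse[al, "age_months"])
    pred <- predictAge(clk, B)
    crEffect(pred[mouse$sample_id], mouse$age_months, mouse$diet)
}
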