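test_that("signed adjacency hits its endpoints and the direct formula", {
    x <- seq_len(10)
    B <- rbind(a = x, b = 2 * x + 3, c = -x + 20) / 25
    rownames(B) <- paste0("chr1:", 1:3 * 100)
    colnames(B) <- paste0("S", 1:10)
    a1 <- signedAdjacency(B, power = 1)
    expect_equal(a1[1, 2], 1)               # cor  1 -> 1
    expect_equal(a1[1, 3], 0)               # cor -1 -> 0
    expect_equal(diag(a1), rep(1, 3), ignore_attr = TRUE)
    # power-2 arithmetic at cor = 0.5 and a random-matrix formula check
    set.seed(33)
    R <- matrix(runif(5 * 12, 0.2, 0.8), 5, 12,
                dimnames = list(paste0("chr1:", 1:5 * 10), paste0("S", 1:12)))
    for (pw in c(1, 2)) {
        got <- signedAdjacency(R, power = pw)
        oracle <- ((1 + cor(t(R))) / 2)^pw
        diag(oracle) <- 1
        expect_equal(got, oracle, tolerance = 1e-12)
    }
    expect_equal(((1 + 0.5) / 2)^2, 0.5625)   # the forced arithmetic case
    # constant CpG: correlation treated as 0
    R2 <- R; R2[2, ] <- 0.4
    expect_message(a2 <- signedAdjacency(R2), "constant")
    expect_equal(a2[2, 4], 0.5)
})

test_that("TOM matches hand arithmetic and the triple-loop oracle", {
    ones <- matrix(1, 4, 4)
    expect_equal(tomSimilarity(ones), ones, ignore_attr = TRUE)
    a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
    w3 <- tomSimilarity(a3)
    expect_equal(w3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))   # = 0.5
    for (s in 1:20) {
        set.seed(300 + s)
        n <- sample(6:10, 1)
        a <- matrix(runif(n * n), n)
        a <- (a + t(a)) / 2
        diag(a) <- 1
        expect_equal(tomSimilarity(a), tomOracle(a), tolerance = 1e-12,
                     ignore_attr = TRUE)
    }
})

test_that("consensus calibration scales to the reference then takes minima", {
    set.seed(35)
    mk <- function() {
        a <- matrix(runif(64, 0, 0.9), 8)
        a <- (a + t(a)) / 2; diag(a) <- 1
        dimnames(a) <- list(paste0("chr1:", 1:8), paste0("chr1:", 1:8))
        a
    }
    t1 <- mk(); t2 <- mk()
    expect_equal(consensusTOM(list(t1, t1)), t1)
    z <- t1 * 0; diag(z) <- 1; dimnames(z) <- dimnames(t1)
    consZ <- consensusTOM(list(t1, z))
    expect_equal(consZ[upper.tri(consZ)], rep(0, 28))
    got <- consensusTOM(list(t1, t2), consensusQuantile = 0.95)
    q <- function(m) quantile(m[upper.tri(m)], 0.95, names = FALSE)
    oracle <- pmin(t1, t2 * q(t1) / q(t2))
    oracle[oracle > 1] <- 1
    diag(oracle) <- 1
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_error(consensusTOM(list(t1, mk()[c(2:8, 1), c(2:8, 1)])), "differ")
})

test_that("planted blocks are recovered exactly at strong separation", {
    pm <- plantedBlockMatrix(nBlocks = 2, blockSize = 30, nNoise = 40,
                             nSamples = 50, withinCor = 0.9, seed = 44)
    tom <- tomSimilarity(signedAdjacency(pm$beta, power = 1))
    asn <- cutModules(tom, deepSplit = 1L, minModuleSize = 25L)
    lab <- moduleLabels(asn)
    nonGrey <- setdiff(unique(lab), "grey")
    expect_length(nonGrey, 2L)
    expect_equal(adjustedRand(lab, pm$truth), 1)
    # a lone block below the size floor yields no modules
    pm2 <- plantedBlockMatrix(nBlocks = 1, blockSize = 10, nNoise = 30,
                              nSamples = 40, seed = 45)
    tom2 <- tomSimilarity(signedAdjacency(pm2$beta, power = 1))
    asn2 <- cutModules(tom2, minModuleSize = 25L)
    expect_equal(unique(moduleLabels(asn2)), "grey")
})

test_that("planted-partition recovery holds across seeds", {
    ok <- vapply(1:5, function(s) {
        pm <- plantedBlockMatrix(nBlocks = 3, blockSize = c(30), nNoise = 50,
                                 nSamples = 60, withinCor = 0.9,
                                 seed = 500 + s)
        tom <- tomSimilarity(signedAdjacency(pm$beta))
        lab <- moduleLabels(cutModules(tom))
        adjustedRand(lab, pm$truth)
    }, 0)
    expect_true(all(ok >= 0.9))
})

test_that("eigengenes behave on degenerate and planted modules", {
    n <- 30
    set.seed(36)
    prof <- runif(n, 0.2, 0.8)
    B <- rbind(prof, prof, prof)
    rownames(B) <- paste0("chr1:", 1:3 * 10)
    colnames(B) <- paste0("S", 1:n)
    asn <- new("ModuleAssignment",
               labels = setNames(rep("blue", 3), rownames(B)),
               minModuleSize = 2L)
    eg <- moduleEigengene(B, asn, "blue")
    expect_equal(unname(eg@kme), rep(1, 3), tolerance = 1e-12)
    expect_equal(mean(eg@scores), 0, tolerance = 1e-12)
    # two perfectly anticorrelated members: |kME| = 1, opposite signs
    B2 <- rbind(prof, 1 - prof)
    rownames(B2) <- paste0("chr1:", 1:2 * 10)
    colnames(B2) <- colnames(B)
    asn2 <- new("ModuleAssignment",
                labels = setNames(rep("blue", 2), rownames(B2)),
                minModuleSize = 2L)
    eg2 <- moduleEigengene(B2, asn2, "blue")
    expect_equal(abs(unname(eg2@kme)), c(1, 1), tolerance = 1e-12)
    expect_equal(sum(sign(eg2@kme)), 0)
    # planted block eigengene matches a dense eigensolver up to sign
    pm <- plantedBlockMatrix(nBlocks = 1, blockSize = 20, nNoise = 0,
                             nSamples = 40, seed = 46)
    asn3 <- new("ModuleAssignment",
                labels = setNames(rep("blue", 20), rownames(pm$beta)),
                minModuleSize = 2L)
    eg3 <- moduleEigengene(pm$beta, asn3, "blue")
    xc <- t(pm$beta - rowMeans(pm$beta))
    sv <- eigen(tcrossprod(xc), symmetric = TRUE)
    ref <- sv$vectors[, 1] * sqrt(sv$values[1])
    agree <- min(sum(abs(eg3@scores - ref)), sum(abs(eg3@scores + ref)))
    expect_lt(agree, 1e-8)
})

test_that("kME pruning greys out planted outliers and dissolves remnants", {
    pm <- plantedBlockMatrix(nBlocks = 1, blockSize = 29, nNoise = 20,
                             nSamples = 50, seed = 47)
    B <- pm$beta
    # plant an uncorrelated impostor inside the module
    set.seed(48)
    B[29, ] <- runif(50, 0.2, 0.8)
    labels <- setNames(ifelse(pm$truth == 1, "blue", "grey"), rownames(B))
    asn <- new("ModuleAssignment", labels = labels, minModuleSize = 25L)
    pruned <- kmePrune(B, asn, minKme = 0.4)
    lab <- moduleLabels(pruned)
    expect_equal(unname(lab[29]), "grey")
    expect_equal(sum(lab != "grey"), 28L)
    # all members strong: unchanged
    asnClean <- new("ModuleAssignment",
                    labels = setNames(ifelse(pm$truth[-29] == 1, "blue",
                                             "grey"), rownames(B)[-29]),
                    minModuleSize = 25L)
    prunedClean <- kmePrune(B[-29, ], asnClean, minKme = 0.4)
    expect_equal(sum(moduleLabels(prunedClean) != "grey"), 28L)
    # a module sliding below the floor dissolves entirely
    pm3 <- plantedBlockMatrix(nBlocks = 1, blockSize = 26, nNoise = 10,
                              nSamples = 50, seed = 49)
    B3 <- pm3$beta
    set.seed(50)
    B3[25, ] <- runif(50); B3[26, ] <- runif(50)
    labels3 <- setNames(ifelse(pm3$truth == 1, "blue", "grey"), rownames(B3))
    asn3 <- new("ModuleAssignment", labels = labels3, minModuleSize = 25L)
    expect_equal(unique(moduleLabels(kmePrune(B3, asn3))), "grey")
})

test_that("a whole-matrix module clock equals the global clock", {
    set.seed(37)
    ages <- runif(24, 1, 27)
    B <- 0.5 + outer(runif(40, -0.15, 0.15), (ages - 14) / 26) +
        matrix(rnorm(40 * 24, 0, 0.03), 40)
    B <- pmin(pmax(B, 0), 1)
    rownames(B) <- paste0("chr1:", seq_len(40) * 100)
    colnames(B) <- paste0("S", seq_len(24))
    asn <- new("ModuleAssignment",
               labels = setNames(rep("blue", 40), rownames(B)),
               minModuleSize = 2L)
    mc <- moduleClock(B, ages, asn, "blue")
    pcaG <- fitPCA(B, nComponents = 1L)
    global <- fitPCClock(pcaG, B, ages)
    expect_equal(predictAge(mc, B), predictAge(global, B), tolerance = 1e-9)
    # a permuted-age training yields a near-null test association
    set.seed(38)
    nulls <- replicate(30, {
        agesPerm <- sample(ages)
        clk <- moduleClock(B, agesPerm, asn, "blue")
        cor(predictAge(clk, B), ages)
    })
    expect_lt(abs(mean(sign(nulls))), 0.6)
})
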