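test_that("feature PCA is train-anchored, oriented and standardized", {
    set.seed(61)
    n <- 50
    ages <- runif(n, 1, 27)
    dominant <- scale(ages)[, 1] + rnorm(n, 0, 0.1)
    # one latent factor carried by two features (features are z-scored
    # internally, so "dominant" means shared, not large-variance)
    F1 <- cbind(f1 = dominant * 10, f2 = dominant + rnorm(n, 0, 0.2),
                f3 = rnorm(n))
    rownames(F1) <- paste0("S", seq_len(n))
    tr <- rownames(F1)[1:35]
    sc <- pcaReduce(F1, tr, setNames(ages, rownames(F1)), nPcs = 2L)
    expect_gt(cor(sc[, 1], dominant), 0.97)
    expect_equal(sd(sc[, 1]), 1, tolerance = 1e-12)
    expect_gt(cor(sc[tr, 1], ages[1:35]), 0)          # orientation
    # zero-variance feature dropped with a warning
    F2 <- cbind(F1, flat = 1)
    expect_warning(pcaReduce(F2, tr, setNames(ages, rownames(F1))), "flat")
    # loadings match a dense eigensolver on a 6-feature toy
    set.seed(62)
    F3 <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(paste0("S", 1:40), paste0("f", 1:6)))
    sc3 <- pcaReduce(F3, rownames(F3), setNames(runif(40), rownames(F3)),
                     nPcs = 2L)
    Z <- scale(F3)
    ev <- eigen(crossprod(Z), symmetric = TRUE)
    oracle <- Z %*% ev$vectors[, 1:2]
    expect_gt(abs(cor(sc3[, 1], oracle[, 1])), 1 - 1e-9)
    expect_gt(abs(cor(sc3[, 2], oracle[, 2])), 1 - 1e-9)
})

test_that("OLS matches the normal equations with classical inference", {
    # 6-point hand dataset
    y <- c(2, 4, 5, 4, 5, 7)
    x <- c(1, 2, 3, 4, 5, 6)
    fit <- olsFit(y, data.frame(x = x))
    o <- olsOracle(y, cbind(x = x))
    expect_equal(unname(fit@coefficients), unname(o$coef), tolerance = 1e-12)
    expect_equal(unname(fit@se), unname(o$se), tolerance = 1e-12)
    # exact linear response
    fit2 <- olsFit(3 + 2 * x, data.frame(x = x))
    expect_equal(unname(fit2@coefficients), c(3, 2), tolerance = 1e-10)
    expect_lt(fit2@pvalue["x"], 1e-12)
    # residuals sum to zero with an intercept
    expect_equal(sum(fit@residuals), 0, tolerance = 1e-10)
    # random full-rank designs against the oracle
    for (s in 1:50) {
        set.seed(600 + s)
        n <- sample(12:30, 1); p <- sample(2:4, 1)
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", 1:p)))
        yy <- rnorm(n)
        f <- olsFit(yy, X)
        oo <- olsOracle(yy, X)
        expect_equal(unname(f@coefficients), unname(oo$coef),
                     tolerance = 1e-8)
        expect_equal(unname(f@se), unname(oo$se), tolerance = 1e-8)
    }
    expect_error(olsFit(rnorm(10), cbind(a = 1:10, b = 2 * (1:10))), "b")
})

test_that("attenuation arithmetic and invariances", {
    expect_equal(attenuationPercent(0.75, 0.63), 16)
    expect_equal(attenuationPercent(1, 1), 0)
    expect_equal(attenuationPercent(0.75, 0.42), 44)
    for (c0 in c(-2, 0.5, 3))
        expect_equal(attenuationPercent(c0 * 0.8, c0 * 0.6),
                     attenuationPercent(0.8, 0.6))
    expect_error(attenuationPercent(0, 1), "zero")
})

test_that("the DNAmAge model family reproduces the attenuation pattern", {
    set.seed(63)
    n <- 120
    age <- runif(n, 1, 27)
    phenoPC1 <- scale(0.5 * scale(age)[, 1] + rnorm(n))[, 1]
    dnam <- 2 + 0.75 * age + 1.2 * phenoPC1 + rnorm(n, 0, 1.5)
    facsPC1 <- scale(0.8 * scale(age)[, 1] + rnorm(n, 0, 0.6))[, 1]
    fits <- dnamAgeModels(dnam, age, phenoPC1, facsPC1)
    b1 <- fits$model1@coefficients["age"]
    b2 <- fits$model2@coefficients["age"]
    expect_lt(b2, b1)       # adding phenotype attenuates the age slope
    expect_gt(fits$model2@coefficients["phenoPC1"], 0)
})

test_that("CR main effect needs both diet groups and recovers a planted shift", {
    set.seed(64)
    n <- 120
    age <- runif(n, 5, 30)
    diet <- rep(c("AL", "CR"), c(95, 25))
    dnam <- 3 + 0.9 * age - 1.2 * (diet == "CR") + rnorm(n, 0, 0.8)
    fit <- crEffect(dnam, age, diet)
    expect_lt(abs(fit@coefficients["cr"] + 1.2), 2 * fit@se["cr"])
    expect_error(crEffect(dnam[diet == "AL"], age[diet == "AL"],
                          diet[diet == "AL"]), "both diet")
    expect_error(crEffect(dnam, age, rep("keto", n)), "AL")
})

test_that("the age-by-CR interaction is centering-invariant and signed right", {
    set.seed(65)
    n <- 150
    age <- runif(n, 4, 30)
    diet <- rep(c("AL", "CR"), c(120, 30))
    dnam <- 2 + 0.8 * age - 0.15 * age * (diet == "CR") + rnorm(n, 0, 0.7)
    fit <- crInteraction(dnam, age, diet)
    expect_lt(abs(fit@coefficients["age:cr"] + 0.15), 2 * fit@se["age:cr"])
    fitC <- crInteraction(dnam, age - mean(age), diet)
    expect_equal(unname(fit@coefficients["age:cr"]),
                 unname(fitC@coefficients["age:cr"]), tolerance = 1e-9)
})

test_that("CR-duration residual correlation is control-anchored", {
    set.seed(66)
    nAl <- 60; nCr <- 20
    ageAl <- runif(nAl, 5, 30)
    dur <- runif(nCr, 6.5, 23)
    ageCr <- 3.2 + dur
    dnamAl <- 1 + 0.9 * ageAl + rnorm(nAl, 0, 0.6)
    dnamCr <- 1 + 0.9 * ageCr - 0.25 * dur + rnorm(nCr, 0, 0.6)
    res <- crDurationResidual(c(dnamAl, dnamCr), c(ageAl, ageCr),
                              rep(c("AL", "CR"), c(nAl, nCr)),
                              c(rep(0, nAl), dur))
    expect_lt(res$r, 0)
    expect_lt(res$p, 0.05)
    # zero planted effect: correlation small over seeds
    rs <- vapply(1:20, function(s) {
        set.seed(700 + s)
        dnamCr0 <- 1 + 0.9 * ageCr + rnorm(nCr, 0, 0.6)
        crDurationResidual(c(dnamAl, dnamCr0), c(ageAl, ageCr),
                           rep(c("AL", "CR"), c(nAl, nCr)),
                           c(rep(0, nAl), dur))$r
    }, 0)
    expect_lt(abs(mean(rs)), 2 / sqrt(nCr))
    expect_error(crDurationResidual(c(dnamAl, dnamCr), c(ageAl, ageCr),
                                    rep(c("AL", "CR"), c(nAl, nCr)),
                                    c(rep(0, nAl), rep(10, nCr))),
                 "equal")
})

test_that("Kruskal-Wallis matches the hand formula and the two-group case", {
    # textbook-style 3-group example, no ties: H by explicit ranks
    g <- rep(c("a", "b", "c"), times = c(5, 5, 5))
    v <- c(27, 2, 4, 18, 7, 9, 25, 1, 3, 11, 34, 12, 15, 29, 22)
    r <- rank(v)
    n <- length(v)
    H <- 12 / (n * (n + 1)) *
        sum(tapply(r, g, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
    got <- kruskalWallis(v, g)
    expect_equal(got$H, H, tolerance = 1e-10)
    expect_equal(got$df, 2)
    # identical distributions: rarely significant
    set.seed(67)
    ps <- vapply(1:100, function(i)
        kruskalWallis(sample(1:30), rep(1:3, 10))$p, 0)
    expect_gte(mean(ps > 0.05), 0.9)
    # two groups: matches a direct kruskal computation run independently
    v2 <- c(3, 1, 4, 1, 5, 9, 2, 6)
    g2 <- rep(c("x", "y"), 4)
    r2 <- rank(v2)
    H2 <- 12 / (8 * 9) * sum(tapply(r2, g2, function(x) 4 * mean(x)^2)) - 27
    tie <- 1 - sum(sapply(table(v2)[table(v2) > 1],
                          function(t) t^3 - t)) / (8^3 - 8)
    expect_equal(kruskalWallis(v2, g2)$H, H2 / tie, tolerance = 1e-10)
    expect_error(kruskalWallis(v2, rep("x", 8)), "2 groups")
})
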