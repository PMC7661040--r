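# Independent oracles, deliberately coded as plain enumerations and
# closed forms so they share no code path with the implementation.

# biweight midcorrelation straight from the weight definition
bicorOracle <- function(x, y) {
    one <- function(v) {
        med <- sort(v)[ceiling(length(v) / 2)]
        if (length(v) %% 2 == 0)
            med <- mean(sort(v)[length(v) / 2 + 0:1])
        madv <- sort(abs(v - med))[ceiling(length(v) / 2)]
        if (length(v) %% 2 == 0)
            madv <- mean(sort(abs(v - med))[length(v) / 2 + 0:1])
        u <- (v - med) / (9 * madv)
        w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
        (v - med) * w
    }
    xt <- one(x); yt <- one(y)
    sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

# topological overlap by explicit triple loop
tomOracle <- function(a) {
    n <- nrow(a)
    w <- diag(1, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
        w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    w
}

# OLS through the normal equations
olsOracle <- function(y, X) {
    X <- cbind(1, X)
    xtx <- solve(t(X) %*% X)
    b <- xtx %*% t(X) %*% y
    res <- y - X %*% b
    s2 <- sum(res^2) / (length(y) - ncol(X))
    list(coef = drop(b), se = sqrt(diag(xtx) * s2))
}

# two-sided Fisher exact p by hypergeometric enumeration over the table
# family with fixed margins
fisherOracle <- function(a, b, c, d) {
    m <- a + b            # module size
    reg <- a + c          # in-region total
    n <- a + b + c + d
    avals <- max(0, reg - (n - m)):min(m, reg)
    probs <- dhyper(avals, m, n - m, reg)
    pObs <- dhyper(a, m, n - m, reg)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exhaustive kNN sliding-window imputation on a small matrix
knnImputeOracle <- function(B, chrom, pos, k = 5, windowBp = 3e6,
                            minShared = 3) {
    out <- B
    for (i in seq_len(nrow(B))) for (j in seq_len(ncol(B))) {
        if (!is.na(B[i, j])) next
        cand <- setdiff(which(chrom == chrom[i] &
                              abs(pos - pos[i]) <= windowBp / 2), i)
        info <- NULL
        for (c in cand) {
            if (is.na(B[c, j])) next
            sh <- which(!is.na(B[i, ]) & !is.na(B[c, ]))
            if (length(sh) < minShared) next
            d <- sqrt(sum((B[i, sh] - B[c, sh])^2)) / sqrt(length(sh))
            info <- rbind(info, c(c, d, abs(pos[c] - pos[i]), pos[c]))
        }
        if (is.null(info)) {
            out[i, j] <- mean(B[i, ], na.rm = TRUE)
        } else {
            o <- order(info[, 2], info[, 3], info[, 4])
            sel <- info[o, 1][seq_len(min(k, nrow(info)))]
            out[i, j] <- mean(B[sel, j])
        }
    }
    out
}
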