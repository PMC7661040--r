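## Clock construction: age-stratified splitting, training-sample PCA,
## the PC1 -> months affine rescaling, elastic-net CpG clocks, prediction
## on frozen training parameters, and the biweight midcorrelation used to
## evaluate them.

#' Split samples into train/test by age group
#'
#' Samples whose (rounded) age in months is listed in `testAges` form the
#' test set; all others train. The partition is deterministic.
#'
#' @param samples data.frame with `sample_id` and `age_months`.
#' @param testAges ages selected for the test set (months).
#' @return list with `trainIds`, `testIds` and the `testAges` used.
#' @export
splitByAge <- function(samples, testAges = c(2, 6, 10, 14, 18, 22, 26)) {
    stopifnot(all(c("sample_id", "age_months") %in% colnames(samples)))
    if (anyNA(samples$age_months)) stop("ages must be present for all samples")
    inTest <- round(samples$age_months) %in% testAges
    if (!any(inTest)) stop("empty test set")
    if (all(inTest)) stop("empty training set")
    list(trainIds = samples$sample_id[!inTest],
         testIds = samples$sample_id[inTest],
         testAges = testAges)
}

.betaOf <- function(x) {
    if (is(x, "BetaMatrix")) betaValues(x) else as.matrix(x)
}

#' Principal component analysis of a (training) beta matrix
#'
#' Centers each site by its training mean (no per-site variance scaling:
#' betas share the common [0,1] scale) and computes an economy-size
#' singular value decomposition of the n_train x n_sites centered matrix;
#' loadings are the right singular vectors. Training scores have zero
#' mean per component by construction.
#'
#' @param x \linkS4class{BetaMatrix} or sites x samples matrix, complete
#'   (post-imputation), restricted to the training samples.
#' @param nComponents number of components to retain.
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(x, nComponents) {
    b <- .betaOf(x)
    if (anyNA(b)) stop("fitPCA requires a complete matrix; impute first")
    n <- ncol(b)
    stopifnot(nComponents >= 1L, nComponents <= min(n - 1L, nrow(b)))
    means <- rowMeans(b)
    xc <- t(b - means)                       # n x p, column-centered
    sv <- svd(xc, nu = 0, nv = nComponents)
    tot <- sum(sv$d^2)
    if (tot < 1e-12) stop("constant matrix: no variance to decompose")
    vf <- (sv$d^2 / tot)[seq_len(nComponents)]
    loadings <- sv$v
    rownames(loadings) <- rownames(b)
    new("PCAModel", siteIds = rownames(b), means = means,
        loadings = loadings, varFraction = vf)
}

#' Project samples onto a fitted PCA
#'
#' Applies the training means and loadings frozen at fit time; never
#' re-centers on new data.
#'
#' @param pca a \linkS4class{PCAModel}.
#' @param x \linkS4class{BetaMatrix} or matrix containing the model sites.
#' @return samples x components score matrix.
#' @export
pcaScores <- function(pca, x) {
    b <- .betaOf(x)
    miss <- setdiff(pca@siteIds, rownames(b))
    if (length(miss))
        stop("matrix lacks ", length(miss), " model sites, e.g. ",
             paste(utils::head(miss, 3), collapse = ", "))
    t(b[pca@siteIds, , drop = FALSE] - pca@means) %*% pca@loadings
}

#' Rescale PC scores to months: the PC clock
#'
#' Regresses training age on the (oriented) component scores by ordinary
#' least squares. Orientation flips each included component so its
#' training score correlates non-negatively with age; with centered
#' scores the intercept equals the mean training age. The slope and
#' intercept are the "months per score unit" rescaling applied unchanged
#' in every later test sample.
#'
#' @param pca a \linkS4class{PCAModel} fitted on the training matrix.
#' @param trainX the training \linkS4class{BetaMatrix}/matrix.
#' @param trainAges ages in months, one per training sample.
#' @param components component indices to include (default 1).
#' @return a \linkS4class{PCClock}.
#' @export
fitPCClock <- function(pca, trainX, trainAges, components = 1L) {
    components <- as.integer(components)
    sc <- pcaScores(pca, trainX)[, components, drop = FALSE]
    if (length(trainAges) != nrow(sc))
        stop("trainAges length must match training samples")
    sds <- apply(sc, 2L, stats::sd)
    if (any(sds < 1e-12)) stop("zero-variance component score")
    orient <- vapply(seq_along(components), function(i) {
        r <- stats::cor(sc[, i], trainAges)
        if (r < 0) -1 else 1
    }, 0)
    sco <- sweep(sc, 2L, orient, `*`)
    fit <- stats::lm.fit(cbind(1, sco), trainAges)
    cf <- fit$coefficients
    new("PCClock", pca = pca, components = components,
        slope = unname(cf[-1L]), intercept = unname(cf[1L]),
        orientation = orient, pairing = NULL)
}

#' Choose how many leading PCs to keep by cross-validation
#'
#' Evaluates the cumulative component sets {1}, {1,2}, ..., {1..maxK} by
#' K-fold cross-validated mean squared error of the age regression on the
#' training scores, and returns the smallest k whose CV MSE is within one
#' standard error of the minimum.
#'
#' @param pca fitted \linkS4class{PCAModel} (at least `maxK` components).
#' @param trainX training matrix the PCA was fitted on.
#' @param trainAges training ages (months).
#' @param folds number of CV folds (>= 2; default 10).
#' @param maxK largest candidate k.
#' @return the selected k (integer).
#' @export
selectComponentsCV <- function(pca, trainX, trainAges, folds = 10L,
                               maxK = ncol(pca@loadings)) {
    stopifnot(folds >= 2L, maxK >= 1L, maxK <= ncol(pca@loadings))
    sc <- pcaScores(pca, trainX)
    n <- length(trainAges)
    fold <- rep_len(seq_len(folds), n)[sample.int(n)]
    cvm <- cvse <- numeric(maxK)
    for (k in seq_len(maxK)) {
        mseFold <- vapply(seq_len(folds), function(f) {
            tr <- fold != f
            X <- cbind(1, sc[, seq_len(k), drop = FALSE])
            cf <- stats::lm.fit(X[tr, , drop = FALSE], trainAges[tr])$coefficients
            cf[is.na(cf)] <- 0
            pred <- X[!tr, , drop = FALSE] %*% cf
            mean((trainAges[!tr] - pred)^2)
        }, 0)
        cvm[k] <- mean(mseFold)
        cvse[k] <- stats::sd(mseFold) / sqrt(folds)
    }
    best <- which.min(cvm)
    which(cvm <= cvm[best] + cvse[best])[1L]
}

#' Train a sparse elastic-net CpG clock
#'
#' Penalized regression of training age on all CpG betas; predictors are
#' standardized internally and the returned weights are on the original
#' beta scale. The penalty is chosen by K-fold cross-validation
#' (minimum-MSE rule) over a logarithmic grid of `nlambda` values, unless
#' a fixed `lambda` is supplied.
#'
#' @param trainX complete training \linkS4class{BetaMatrix}/matrix.
#' @param trainAges training ages (months).
#' @param alphaMix elastic-net mixing parameter (default 0.5).
#' @param folds CV folds (default 10).
#' @param nlambda penalty grid size (default 100).
#' @param lambda optional fixed penalty (skips CV).
#' @return an \linkS4class{EnetClock}; the support (CpGs with non-zero
#'   weight) is reported via a message.
#' @export
fitEnetClock <- function(trainX, trainAges, alphaMix = 0.5, folds = 10L,
                         nlambda = 100L, lambda = NULL) {
    b <- .betaOf(trainX)
    if (anyNA(b)) stop("complete matrix required")
    X <- t(b)
    if (is.null(lambda)) {
        cvfit <- glmnet::cv.glmnet(X, trainAges, alpha = alphaMix,
                                   nfolds = folds, nlambda = nlambda,
                                   standardize = TRUE)
        lambda <- cvfit$lambda.min
        fitObj <- cvfit$glmnet.fit
    } else {
        fitObj <- glmnet::glmnet(X, trainAges, alpha = alphaMix,
                                 lambda = lambda, standardize = TRUE)
    }
    cf <- as.matrix(stats::coef(fitObj, s = lambda))[, 1L]
    if (!all(is.finite(cf))) stop("no finite elastic-net solution")
    w <- cf[-1L][cf[-1L] != 0]
    message("elastic-net support: ", length(w), " of ", nrow(b), " CpGs")
    new("EnetClock", weights = w, intercept = unname(cf[1L]),
        alphaMix = alphaMix, lambda = lambda)
}

#' Predict DNAmAge in months
#'
#' Applies the training means, loadings and weights frozen at fit time.
#' For a transferred \linkS4class{PCClock} carrying a cross-species site
#' pairing, rows are pulled from the target matrix by the paired target
#' ids and aligned to the source-side model sites.
#'
#' @param clock a \linkS4class{PCClock} or \linkS4class{EnetClock}.
#' @param x \linkS4class{BetaMatrix} or matrix to predict on.
#' @return named vector of DNAmAge predictions (months).
#' @export
setGeneric("predictAge", function(clock, x) standardGeneric("predictAge"))

#' @rdname predictAge
setMethod("predictAge", "PCClock", function(clock, x) {
    b <- .betaOf(x)
    if (!is.null(clock@pairing) &&
        !all(clock@pca@siteIds %in% rownames(b))) {
        pr <- clock@pairing
        miss <- setdiff(pr$tgt, rownames(b))
        if (length(miss))
            stop("matrix lacks ", length(miss), " paired target sites, e.g. ",
                 paste(utils::head(miss, 3), collapse = ", "))
        b <- b[pr$tgt, , drop = FALSE]
        rownames(b) <- pr$src
    }
    sc <- pcaScores(clock@pca, b)[, clock@components, drop = FALSE]
    sc <- sweep(sc, 2L, clock@orientation, `*`)
    drop(clock@intercept + sc %*% clock@slope)
})

#' @rdname predictAge
setMethod("predictAge", "EnetClock", function(clock, x) {
    b <- .betaOf(x)
    miss <- setdiff(names(clock@weights), rownames(b))
    if (length(miss))
        stop("matrix lacks ", length(miss), " clock sites, e.g. ",
             paste(utils::head(miss, 3), collapse = ", "))
    drop(clock@intercept +
         t(b[names(clock@weights), , drop = FALSE]) %*% clock@weights)
})

#' Biweight midcorrelation
#'
#' Robust correlation with Tukey biweight weights `w = (1 - u^2)^2` for
#' `|u| < 1`, where `u_i = (x_i - median(x)) / (9 * mad(x))` and `mad` is
#' the (unscaled) median absolute deviation from the median. When either
#' vector has zero MAD the estimator is undefined and the function falls
#' back to the Pearson correlation (with a message).
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant vector")
    madu <- function(v) stats::median(abs(v - stats::median(v)))
    mx <- madu(x); my <- madu(y)
    if (mx == 0 || my == 0) {
        message("zero MAD: falling back to Pearson correlation")
        return(stats::cor(x, y))
    }
    wt <- function(v, m) {
        u <- (v - stats::median(v)) / (9 * m)
        w <- (1 - u^2)^2
        w[abs(u) >= 1] <- 0
        (v - stats::median(v)) * w
    }
    xt <- wt(x, mx); yt <- wt(y, my)
    sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}
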