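## Covariate-adjusted aging associations: phenotype / FACS dimension
## reduction, the DNAmAge regression model family, attenuation, caloric
## restriction effects, and rank-based group comparisons.

#' Reduce a feature table to training-anchored principal components
#'
#' Features are z-scored with training means and standard deviations
#' (zero-s.d. features dropped with a warning), the PCA is fitted on the
#' training samples only, and the training loadings are applied to every
#' sample. PC1 is oriented so its training score correlates
#' non-negatively with training age, and each returned score column is
#' standardized to s.d. 1 in the analytic (full) sample.
#'
#' @param features data.frame/matrix of samples x numeric features with
#'   sample ids as rownames.
#' @param trainIds ids of the training samples.
#' @param ages named vector of ages (months) covering at least the
#'   training samples (used for PC1 orientation).
#' @param nPcs number of components to return.
#' @return samples x nPcs score matrix (s.d. 1 per column).
#' @export
pcaReduce <- function(features, trainIds, ages, nPcs = 1L) {
    X <- as.matrix(features)
    stopifnot(ncol(X) >= 2L, all(trainIds %in% rownames(X)))
    tr <- X[trainIds, , drop = FALSE]
    mu <- colMeans(tr)
    sdv <- apply(tr, 2L, stats::sd)
    drop0 <- sdv < 1e-12
    if (any(drop0)) {
        warning("dropping zero-s.d. feature(s): ",
                paste(colnames(X)[drop0], collapse = ", "))
        X <- X[, !drop0, drop = FALSE]
        mu <- mu[!drop0]; sdv <- sdv[!drop0]
    }
    Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
    sv <- svd(Z[trainIds, , drop = FALSE], nu = 0,
              nv = min(nPcs, ncol(Z)))
    sc <- Z %*% sv$v
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    r1 <- stats::cor(sc[trainIds, 1L], ages[trainIds])
    if (!is.na(r1) && r1 < 0) sc[, 1L] <- -sc[, 1L]
    sweep(sc, 2L, apply(sc, 2L, stats::sd), `/`)
}

#' Ordinary least squares with classical inference
#'
#' Closed-form least squares on the named design columns (an intercept is
#' added), with classical (non-robust) standard errors and two-sided
#' t-test p-values.
#'
#' @param y response vector.
#' @param design data.frame/matrix of named predictor columns.
#' @return a \linkS4class{RegressionFit}.
#' @export
olsFit <- function(y, design) {
    X <- cbind(`(Intercept)` = 1, as.matrix(design))
    n <- length(y)
    p <- ncol(X)
    if (n <= p) stop("more terms than observations")
    qx <- qr(X)
    if (qx$rank < p) {
        bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
        stop("rank-deficient design; collinear term(s): ",
             paste(bad, collapse = ", "))
    }
    cf <- qr.coef(qx, y)
    res <- y - drop(X %*% cf)
    df <- n - p
    sigma2 <- sum(res^2) / df
    xtxInv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
    se <- sqrt(diag(xtxInv) * sigma2)
    names(se) <- colnames(X)
    tv <- cf / se
    pv <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    new("RegressionFit", coefficients = cf, se = se, tvalue = tv,
        pvalue = pv, n = as.integer(n), df = as.integer(df),
        residuals = res, sigma = sqrt(sigma2))
}

#' Percent attenuation of a coefficient between nested models
#'
#' `100 * (before - after) / before`: how much of an association is
#' explained away when a covariate is added.
#'
#' @param before,after the coefficient in the smaller / larger model.
#' @return percent attenuation.
#' @export
attenuationPercent <- function(before, after) {
    if (before == 0) stop("attenuation undefined for a zero base coefficient")
    100 * (before - after) / before
}

#' DNAmAge regression model family
#'
#' The nested models relating DNAmAge to chronological age, physical
#' function (phenotype PC1) and cell composition (FACS PC1, optionally
#' the first `nFacsPcs` FACS PCs): model 1 `dnamAge ~ age`, model 2 adds
#' `phenoPC1`, model 3 adds the FACS component(s).
#'
#' @param dnamAge DNAmAge (months).
#' @param age chronological age (months).
#' @param phenoPC1 standardized phenotype PC1.
#' @param facsPCs matrix (or vector) of standardized FACS PCs.
#' @param nFacsPcs how many FACS PCs model 3 adjusts for (default 1).
#' @return named list of \linkS4class{RegressionFit}s (`model1..model3`).
#' @export
dnamAgeModels <- function(dnamAge, age, phenoPC1, facsPCs, nFacsPcs = 1L) {
    facsPCs <- as.matrix(facsPCs)[, seq_len(nFacsPcs), drop = FALSE]
    colnames(facsPCs) <- paste0("facsPC", seq_len(ncol(facsPCs)))
    list(
        model1 = olsFit(dnamAge, data.frame(age = age)),
        model2 = olsFit(dnamAge, data.frame(age = age, phenoPC1 = phenoPC1)),
        model3 = olsFit(dnamAge, data.frame(age = age, phenoPC1 = phenoPC1,
                                            facsPCs)))
}

.dietCheck <- function(diet) {
    diet <- as.character(diet)
    if (!all(diet %in% c("AL", "CR"))) stop("diet must be 'AL' or 'CR'")
    if (length(unique(diet)) < 2L) stop("both diet groups must be present")
    diet
}

#' Age-adjusted caloric restriction effect on DNAmAge
#'
#' OLS of DNAmAge on chronological age and a CR indicator; the `cr`
#' coefficient is the average CR displacement in months.
#'
#' @param dnamAge DNAmAge (months).
#' @param age chronological age (months).
#' @param diet "AL"/"CR" per animal.
#' @return a \linkS4class{RegressionFit}.
#' @export
crEffect <- function(dnamAge, age, diet) {
    diet <- .dietCheck(diet)
    olsFit(dnamAge, data.frame(age = age, cr = as.numeric(diet == "CR")))
}

#' Age-by-CR interaction model
#'
#' Adds the product term `age * CR` to [crEffect()]'s model; a negative
#' interaction coefficient means the CR deceleration grows with age
#' (hence with time on diet).
#'
#' @inheritParams crEffect
#' @return a \linkS4class{RegressionFit} with terms age, cr, age:cr.
#' @export
crInteraction <- function(dnamAge, age, diet) {
    diet <- .dietCheck(diet)
    cr <- as.numeric(diet == "CR")
    olsFit(dnamAge, data.frame(age = age, cr = cr, `age:cr` = age * cr,
                               check.names = FALSE))
}

#' Correlation of the control-anchored age residual with CR duration
#'
#' Fits DNAmAge on age in the control (AL) animals only, applies that
#' equation to the CR animals, and correlates their residuals
#' (observed - predicted) with time on diet (Pearson, two-sided p).
#'
#' @inheritParams crEffect
#' @param duration months on CR per animal (ignored for AL).
#' @return list with `r`, `p` and the per-CR-animal `residuals`.
#' @export
crDurationResidual <- function(dnamAge, age, diet, duration) {
    diet <- .dietCheck(diet)
    ctrl <- diet == "AL"
    if (sum(ctrl) < 3L || sum(!ctrl) < 3L)
        stop("need at least 3 control and 3 CR animals")
    fit <- olsFit(dnamAge[ctrl], data.frame(age = age[ctrl]))
    pred <- fit@coefficients["(Intercept)"] + fit@coefficients["age"] * age[!ctrl]
    resid <- dnamAge[!ctrl] - pred
    dur <- duration[!ctrl]
    if (stats::sd(dur) == 0)
        stop("all CR durations equal: correlation undefined")
    ct <- stats::cor.test(resid, dur)
    list(r = unname(ct$estimate), p = ct$p.value, residuals = resid)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees
#' of freedom (delegates to `stats::kruskal.test`).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `H`, `df` and `p`.
#' @export
kruskalWallis <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
    if (any(table(groups) == 0L)) stop("empty group")
    kt <- stats::kruskal.test(values, groups)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}
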