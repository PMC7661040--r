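#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start strand granges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

## Central container: CpG sites x samples beta-value grid with explicit
## missingness, carried as a RangedSummarizedExperiment whose single
## "beta" assay holds fractions in [0,1] (NA = below-coverage / absent).

#' BetaMatrix: a sites-by-samples methylation fraction matrix
#'
#' `BetaMatrix` extends `RangedSummarizedExperiment` with a single assay
#' named `"beta"`. Rows are CpG sites (width-1 `GRanges`, sorted by
#' chromosome then position), columns are samples. Missing entries (below
#' the coverage cutoff, or never observed) are `NA`. Sample metadata —
#' species, age in months, diet, time on caloric restriction, tissue and
#' train/test split — lives in `colData`.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}.
#' @export
setClass("BetaMatrix", contains = "RangedSummarizedExperiment")

.validBetaMatrix <- function(object) {
    msg <- NULL
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (any(b < 0 | b > 1, na.rm = TRUE))
            msg <- c(msg, "beta values must lie in [0,1]")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        if (any(GenomicRanges::width(rr) != 1L))
            msg <- c(msg, "sites must be width-1 positions")
        o <- order(as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
        if (anyDuplicated(paste0(GenomicRanges::seqnames(rr), ":",
                                 GenomicRanges::start(rr))))
            msg <- c(msg, "duplicate (chrom, pos) sites")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("BetaMatrix", .validBetaMatrix)

#' Construct a BetaMatrix
#'
#' @param beta numeric matrix (sites x samples), values in [0,1] or NA.
#' @param sites `GRanges` of width-1 CpG positions (one per row of `beta`),
#'   or a character vector of `"chrom:pos"` identifiers.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample
#'   metadata; rownames (or a `sample_id` column) must match `colnames(beta)`.
#' @return a `BetaMatrix`, rows sorted by (chrom, pos).
#' @export
BetaMatrix <- function(beta, sites, sampleData = NULL) {
    beta <- as.matrix(beta)
    if (is.character(sites))
        sites <- .parseSiteIds(sites)
    stopifnot(is(sites, "GRanges"), length(sites) == nrow(beta))
    o <- order(as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites))
    sites <- sites[o]
    beta <- beta[o, , drop = FALSE]
    rownames(beta) <- siteIdOf(sites)
    names(sites) <- rownames(beta)
    if (is.null(sampleData)) {
        sampleData <- S4Vectors::DataFrame(row.names = colnames(beta))
    } else {
        sampleData <- S4Vectors::DataFrame(sampleData)
        if (is.null(rownames(sampleData)) && "sample_id" %in% colnames(sampleData))
            rownames(sampleData) <- sampleData$sample_id
        sampleData <- sampleData[colnames(beta), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta), rowRanges = sites, colData = sampleData)
    new("BetaMatrix", se)
}

## ---- methylation call set -------------------------------------------------

#' Per-sample methylation calls
#'
#' One record per CpG: position, beta fraction and read coverage.
#'
#' @slot sampleId single sample identifier.
#' @slot calls `GRanges` with metadata columns `beta` (in [0,1]) and
#'   `coverage` (non-negative integer), sorted by (chrom, pos).
#' @export
setClass("MethylationCallSet",
         representation(sampleId = "character", calls = "GRanges"))

setValidity("MethylationCallSet", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
    mc <- S4Vectors::mcols(object@calls)
    if (!all(c("beta", "coverage") %in% colnames(mc)))
        msg <- c(msg, "calls need 'beta' and 'coverage' columns")
    else {
        if (any(mc$beta < 0 | mc$beta > 1, na.rm = TRUE))
            msg <- c(msg, "beta outside [0,1]")
        if (any(mc$coverage < 0)) msg <- c(msg, "negative coverage")
        if (anyDuplicated(paste0(GenomicRanges::seqnames(object@calls), ":",
                                 GenomicRanges::start(object@calls))))
            msg <- c(msg, "one record per site per sample violated")
    }
    if (is.null(msg)) TRUE else msg
})

MethylationCallSet <- function(sampleId, calls) {
    o <- order(as.character(GenomicRanges::seqnames(calls)),
               GenomicRanges::start(calls))
    new("MethylationCallSet", sampleId = sampleId, calls = calls[o])
}

## ---- clock models ---------------------------------------------------------

#' Principal component model of a training beta matrix
#'
#' Centering is by per-site training means only (betas share the common
#' [0,1] scale, so no per-site variance scaling is applied).
#'
#' @slot siteIds ordered CpG identifiers ("chrom:pos").
#' @slot means per-site training means.
#' @slot loadings sites x components matrix, orthonormal columns.
#' @slot varFraction fraction of total variance per retained component.
#' @export
setClass("PCAModel",
         representation(siteIds = "character", means = "numeric",
                        loadings = "matrix", varFraction = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- NULL
    p <- length(object@siteIds)
    if (nrow(object@loadings) != p || length(object@means) != p)
        msg <- c(msg, "siteIds, means and loadings rows must agree")
    if (ncol(object@loadings) > 0) {
        g <- crossprod(object@loadings)
        if (max(abs(g - diag(ncol(g)))) > 1e-6)
            msg <- c(msg, "loadings columns must be orthonormal")
    }
    vf <- object@varFraction
    if (length(vf) && (any(vf < -1e-12 | vf > 1 + 1e-12) ||
                       any(diff(vf) > 1e-12) || sum(vf) > 1 + 1e-8))
        msg <- c(msg, "varFraction must be in [0,1], non-increasing, sum <= 1")
    if (is.null(msg)) TRUE else msg
})

#' PC-based DNAmAge clock
#'
#' Prediction is `intercept + sum_c slope_c * orientation_c * score_c`,
#' an affine rescale of (oriented) PC scores into months. Orientation is
#' chosen at fit time so each component's training score correlates
#' non-negatively with age.
#'
#' @slot pca the underlying \linkS4class{PCAModel}.
#' @slot components component indices used (default 1).
#' @slot slope months per oriented score unit, one per component.
#' @slot intercept months.
#' @slot orientation +1/-1 per component.
#' @slot pairing optional two-column data.frame (`src`, `tgt`) carried by
#'   cross-species transferred clocks; `predictAge` uses it to pull
#'   target-assembly rows for the source-side sites.
#' @export
setClass("PCClock",
         representation(pca = "PCAModel", components = "integer",
                        slope = "numeric", intercept = "numeric",
                        orientation = "numeric", pairing = "ANY"),
         prototype(pairing = NULL))

#' Sparse elastic-net CpG clock
#'
#' Prediction is `intercept + sum_j weight_j * beta_j` over the (small)
#' support of CpGs with non-zero weight, on the original beta scale.
#'
#' @slot weights named numeric vector, names are CpG ids of the support.
#' @slot intercept months.
#' @slot alphaMix elastic-net mixing parameter in [0,1].
#' @slot lambda selected penalty.
#' @export
setClass("EnetClock",
         representation(weights = "numeric", intercept = "numeric",
                        alphaMix = "numeric", lambda = "numeric"))

## ---- chain alignments -----------------------------------------------------

#' Block-wise source-to-target coordinate map (UCSC chain)
#'
#' @slot blocks data.frame of ungapped alignment blocks with absolute
#'   0-based half-open coordinates: chainId, score, srcChrom, srcStart,
#'   srcEnd, tgtChrom, tgtSize, tgtStrand, tgtStart, tgtEnd (strand-local),
#'   fileOrder.
#' @export
setClass("ChainAlignment", representation(blocks = "data.frame"))

setValidity("ChainAlignment", function(object) {
    b <- object@blocks
    need <- c("chainId", "score", "srcChrom", "srcStart", "srcEnd",
              "tgtChrom", "tgtSize", "tgtStrand", "tgtStart", "tgtEnd",
              "fileOrder")
    if (!all(need %in% colnames(b))) return("missing block columns")
    if (any((b$srcEnd - b$srcStart) != (b$tgtEnd - b$tgtStart)))
        return("ungapped blocks must have equal source/target lengths")
    TRUE
})

## ---- modules --------------------------------------------------------------

#' CpG-to-module assignment
#'
#' Colour labels by decreasing module size from a fixed palette;
#' `"grey"` is the reserved unassigned label.
#'
#' @slot labels named character vector, one label per CpG id.
#' @slot minModuleSize the size floor the assignment was built with.
#' @export
setClass("ModuleAssignment",
         representation(labels = "character", minModuleSize = "integer"))

setValidity("ModuleAssignment", function(object) {
    tab <- table(object@labels[object@labels != "grey"])
    if (length(tab) && any(tab < object@minModuleSize))
        return("non-grey module below minModuleSize")
    TRUE
})

#' Module eigengene
#'
#' First principal component of the centered module submatrix; per-sample
#' scores have zero mean and the sign is oriented so the mean kME over
#' module members is non-negative.
#'
#' @slot module module label.
#' @slot scores named per-sample scores, zero mean.
#' @slot kme named per-CpG correlation with the scores (all CpGs).
#' @export
setClass("Eigengene",
         representation(module = "character", scores = "numeric",
                        kme = "numeric"))

## ---- regression fits ------------------------------------------------------

#' Ordinary least-squares fit summary
#'
#' @slot coefficients,se,tvalue,pvalue named per-term vectors.
#' @slot n sample count; @slot df residual degrees of freedom.
#' @slot residuals per-sample residuals; @slot sigma residual s.d.
#' @export
setClass("RegressionFit",
         representation(coefficients = "numeric", se = "numeric",
                        tvalue = "numeric", pvalue = "numeric",
                        n = "integer", df = "integer",
                        residuals = "numeric", sigma = "numeric"))
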