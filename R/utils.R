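## Internal helpers shared across modules.

#' Site identifiers of a GRanges / BetaMatrix
#'
#' CpG sites are identified as `"chrom:pos"` (1-based position of the C).
#' @param x a `GRanges` of width-1 sites.
#' @return character vector of ids.
#' @keywords internal
siteIdOf <- function(x) {
    paste0(as.character(GenomicRanges::seqnames(x)), ":",
           GenomicRanges::start(x))
}

.parseSiteIds <- function(ids) {
    parts <- regmatches(ids, regexpr(":", ids), invert = TRUE)
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- as.integer(vapply(parts, `[`, "", 2L))
    if (anyNA(pos)) stop("malformed site id(s): expected 'chrom:pos'")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
}

## Run code under a temporary RNG state so generators are seed-local.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Deterministic (chrom, pos) ordering used everywhere sites are sorted.
.siteOrder <- function(gr) {
    order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
}

#' @describeIn BetaMatrix beta-value assay (sites x samples, NA = missing)
#' @param x a `BetaMatrix`.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn BetaMatrix `"chrom:pos"` ids of the sites
#' @export
siteIds <- function(x) rownames(x)

#' @describeIn BetaMatrix sample identifiers
#' @export
sampleIds <- function(x) colnames(x)

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around `mclust::adjustedRandIndex`, used when scoring
#' module recovery against a planted truth.
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index in [-1, 1].
#' @export
adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

setMethod("show", "BetaMatrix", function(object) {
    b <- betaValues(object)
    cat("BetaMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
    cat(sprintf("  missing: %.1f%% of entries\n", 100 * mean(is.na(b))))
    callNextMethod()
})

setMethod("show", "MethylationCallSet", function(object) {
    cat("MethylationCallSet for sample", object@sampleId, "with",
        length(object@calls), "CpG records\n")
})

setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", length(object@siteIds), "sites,",
        ncol(object@loadings), "components retained\n")
    if (length(object@varFraction))
        cat(sprintf("  PC1 variance fraction: %.3f\n", object@varFraction[1]))
})

setMethod("show", "PCClock", function(object) {
    cat("PCClock on components {", paste(object@components, collapse = ","),
        "}: intercept ", round(object@intercept, 3), " months, slope(s) ",
        paste(round(object@slope, 4), collapse = ","), "\n", sep = "")
    if (!is.null(object@pairing))
        cat("  cross-species pairing over", nrow(object@pairing), "sites\n")
})

setMethod("show", "EnetClock", function(object) {
    cat("EnetClock: support of", length(object@weights),
        "CpGs, intercept", round(object@intercept, 3), "months\n")
})

setMethod("show", "ChainAlignment", function(object) {
    cat("ChainAlignment:", length(unique(object@blocks$chainId)), "chains,",
        nrow(object@blocks), "ungapped blocks\n")
})

setMethod("show", "ModuleAssignment", function(object) {
    tab <- sort(table(object@labels), decreasing = TRUE)
    cat("ModuleAssignment over", length(object@labels), "CpGs:\n")
    print(tab)
})

setMethod("show", "RegressionFit", function(object) {
    cat("RegressionFit (n =", object@n, "):\n")
    print(data.frame(estimate = object@coefficients, se = object@se,
                     t = object@tvalue, p = object@pvalue))
})

#' Module labels of an assignment
#' @param x a `ModuleAssignment`.
#' @return named character vector of labels ("grey" = unassigned).
#' @export
moduleLabels <- function(x) x@labels

#' Coefficient table of a RegressionFit
#' @param fit a `RegressionFit`.
#' @return data.frame with estimate, se, t, p per term.
#' @export
coefTable <- function(fit) {
    data.frame(term = names(fit@coefficients), estimate = fit@coefficients,
               se = fit@se, t = fit@tvalue, p = fit@pvalue,
               row.names = NULL)
}
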