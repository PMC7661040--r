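## kNN sliding-window imputation: a missing beta at (site, sample) is the
## average of the k nearest neighbouring CpGs -- by Euclidean distance
## between site profiles -- within a genomic window on the same chromosome.

#' Impute missing beta values with a kNN sliding genomic window
#'
#' For a missing entry at (site i, sample j), candidate neighbours are the
#' other CpGs on the same chromosome within `windowBp / 2` of site i
#' (window centered on the target) that have an observed value in sample
#' j. Candidates are ranked by the Euclidean distance between the two
#' sites' beta profiles over samples where both are observed, divided by
#' the square root of the shared-sample count (normalising unequal
#' overlap); candidates sharing fewer than `minSharedSamples` observations
#' are excluded. Ties are broken by smaller genomic distance, then lower
#' position. The imputed value is the mean over the top `k` candidates'
#' values in sample j; with fewer than `k` eligible candidates all are
#' used, and with none the site's own mean across observed samples is
#' substituted (counted and reported).
#'
#' Distances are computed on demand per chromosome; no site-by-site
#' distance matrix is ever materialised.
#'
#' @param x a complete-enough \linkS4class{BetaMatrix} (typically after
#'   [filterSites()]).
#' @param k neighbour count (default 5).
#' @param windowBp window span in bp (default 3e6, i.e. +/- 1.5 Mb).
#' @param minSharedSamples minimum shared observed samples for a candidate.
#' @return a \linkS4class{BetaMatrix} with no missing entries; previously
#'   present values are untouched.
#' @export
imputeKnnWindow <- function(x, k = 5L, windowBp = 3e6, minSharedSamples = 3L) {
    stopifnot(k >= 1L, windowBp > 0)
    b <- betaValues(x)
    if (!anyNA(b)) return(x)
    gr <- SummarizedExperiment::rowRanges(x)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    half <- windowBp / 2
    nFallback <- 0L
    for (ch in unique(chrom)) {
        rows <- which(chrom == ch)
        P <- pos[rows]              # sorted within chromosome
        B <- b[rows, , drop = FALSE]
        fill <- B                   # imputations land here, so every
        obs <- !is.na(B)            # distance uses original observations
        todo <- which(rowSums(obs) < ncol(B))
        for (ii in todo) {
            lo <- findInterval(P[ii] - half, P) + 1L
            if (lo > 1L && P[lo - 1L] >= P[ii] - half) lo <- lo - 1L
            hi <- findInterval(P[ii] + half, P)
            cand <- setdiff(lo:hi, ii)
            miss <- which(!obs[ii, ])
            if (length(cand)) {
                C <- B[cand, , drop = FALSE]
                sq <- sweep(C, 2L, B[ii, ])^2
                nsh <- rowSums(!is.na(sq))
                d <- sqrt(rowSums(sq, na.rm = TRUE)) / sqrt(nsh)
                d[nsh < minSharedSamples] <- Inf
                gd <- abs(P[cand] - P[ii])
                rk <- order(d, gd, P[cand])
                for (j in miss) {
                    elig <- rk[is.finite(d[rk]) & obs[cand[rk], j]]
                    if (length(elig)) {
                        sel <- elig[seq_len(min(k, length(elig)))]
                        fill[ii, j] <- mean(C[sel, j])
                    } else {
                        own <- mean(B[ii, obs[ii, ]])
                        if (!is.finite(own))
                            stop("site ", rownames(B)[ii],
                                 ": no eligible neighbours and no own observations")
                        fill[ii, j] <- own
                        nFallback <- nFallback + 1L
                    }
                }
            } else {
                own <- mean(B[ii, obs[ii, ]])
                if (!is.finite(own))
                    stop("site ", rownames(B)[ii],
                         ": no eligible neighbours and no own observations")
                fill[ii, miss] <- own
                nFallback <- nFallback + length(miss)
            }
        }
        b[rows, ] <- fill
    }
    if (nFallback)
        message(nFallback, " entries imputed by own-site mean fallback")
    out <- x
    SummarizedExperiment::assay(out, "beta") <- b
    out
}
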