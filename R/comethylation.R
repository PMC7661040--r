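## Consensus co-methylation networks: signed adjacency, topological
## overlap, quantile-calibrated consensus, a dynamic-hybrid-style tree
## cut, eigengene / kME pruning, and module-specific clocks.

.modulePalette <- c("blue", "pink", "purple", "green", "yellow", "brown",
                    "red", "black", "turquoise", "magenta", "cyan", "tan",
                    "salmon", "midnightblue", "lightcyan")

#' Signed co-methylation adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ power` with Pearson correlation computed
#' across samples (`method = "bicor"` substitutes the biweight
#' midcorrelation). Correlations of constant CpGs are set to 0 (reported);
#' the diagonal is 1.
#'
#' @param x \linkS4class{BetaMatrix} or sites x samples matrix, complete,
#'   with at least 3 samples.
#' @param power soft-threshold exponent (default 1).
#' @param method `"pearson"` (default) or `"bicor"`.
#' @return symmetric sites x sites adjacency in [0,1].
#' @export
signedAdjacency <- function(x, power = 1, method = c("pearson", "bicor")) {
    method <- match.arg(method)
    b <- .betaOf(x)
    stopifnot(ncol(b) >= 3L, power > 0)
    if (anyNA(b)) stop("complete matrix required")
    if (method == "pearson") {
        cc <- suppressWarnings(stats::cor(t(b)))
    } else {
        n <- nrow(b)
        cc <- diag(1, n)
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
            cc[i, j] <- cc[j, i] <- bicor(b[i, ], b[j, ])
    }
    if (anyNA(cc)) {
        message(sum(is.na(cc[upper.tri(cc)])),
                " correlations involving constant CpGs set to 0")
        cc[is.na(cc)] <- 0
    }
    a <- ((1 + cc) / 2)^power
    diag(a) <- 1
    dimnames(a) <- list(rownames(b), rownames(b))
    a
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`; the diagonal is 1.
#'
#' @param a square symmetric adjacency in [0,1] with unit diagonal.
#' @return symmetric TOM in [0,1].
#' @export
tomSimilarity <- function(a) {
    stopifnot(is.matrix(a), nrow(a) == ncol(a))
    if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric")
    aa <- crossprod(a)                 # = a %*% a for symmetric a
    l <- aa - 2 * a                    # removes the u = i and u = j terms
    k <- rowSums(a) - 1
    denom <- outer(k, k, pmin) + 1 - a
    w <- (l + a) / denom
    diag(w) <- 1
    w[w < 0] <- 0
    w[w > 1] <- 1
    dimnames(w) <- dimnames(a)
    w
}

#' Consensus of several topological overlap matrices
#'
#' Each TOM is rescaled so that its `consensusQuantile` quantile of
#' off-diagonal values matches that of the first (reference) TOM, then
#' the element-wise minimum is taken and clipped to [0,1]. Calibrating to
#' a fixed reference makes the operation order-dependent only through the
#' choice of reference.
#'
#' @param toms list of TOMs over identical site lists (same order).
#' @param consensusQuantile calibration quantile (default 0.95).
#' @return the consensus TOM.
#' @export
consensusTOM <- function(toms, consensusQuantile = 0.95) {
    stopifnot(length(toms) >= 1L)
    rn <- rownames(toms[[1L]])
    for (tm in toms[-1L])
        if (!identical(rownames(tm), rn)) stop("site lists differ across TOMs")
    offq <- function(tm) stats::quantile(tm[upper.tri(tm)],
                                         consensusQuantile, names = FALSE)
    ref <- offq(toms[[1L]])
    cons <- toms[[1L]]
    for (tm in toms[-1L]) {
        q <- offq(tm)
        sc <- if (q > 0) ref / q else 1     # degenerate flat TOM: no rescale
        cons <- pmin(cons, tm * sc)
    }
    cons[cons < 0] <- 0
    cons[cons > 1] <- 1
    diag(cons) <- 1
    cons
}

.deepSplitParams <- function(deepSplit) {
    stopifnot(deepSplit %in% 0:4)
    mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deepSplit + 1L]
    list(maxCoreScatter = mcs, minGap = (1 - mcs) * 3 / 4)
}

## Per-dendrogram-node statistics: subtree size, mean internal merge
## height (core scatter), and the height at which the subtree attaches
## to the rest of the tree.
.nodeStats <- function(hc) {
    m <- hc$merge
    n <- nrow(m) + 1L
    size <- integer(nrow(m))
    hsum <- numeric(nrow(m))
    attach <- rep(Inf, nrow(m))
    for (i in seq_len(nrow(m))) {
        s <- 0L; hs <- 0
        for (child in m[i, ]) {
            if (child < 0L) s <- s + 1L
            else {
                s <- s + size[child]
                hs <- hs + hsum[child]
                attach[child] <- hc$height[i]
            }
        }
        size[i] <- s
        hsum[i] <- hs + hc$height[i]
    }
    list(size = size, scatter = hsum / pmax(size - 1L, 1L), attach = attach)
}

.subtreeTips <- function(hc, node) {
    out <- integer(0)
    stack <- node
    while (length(stack)) {
        i <- stack[1L]; stack <- stack[-1L]
        for (child in hc$merge[i, ]) {
            if (child < 0L) out <- c(out, -child)
            else stack <- c(stack, child)
        }
    }
    out
}

#' Detect co-methylation modules by an adaptive tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a dynamic-hybrid-style branch decomposition (without the
#' PAM-like reassignment stage). Every dendrogram subtree below the cut
#' height (`cutHeightFrac` times the maximum merge height) is a candidate
#' branch; it qualifies as a module when (i) it has at least
#' `minModuleSize` tips, (ii) its core scatter -- the mean of its internal
#' merge heights -- stays below `ref + maxCoreScatter * (cut - ref)`,
#' with `ref` the 5th percentile of all merge heights, and (iii) it is
#' separated from the rest of the tree by a gap of at least
#' `minGap * (cut - ref)` between its own top merge and the height at
#' which it attaches to the tree. Minimal qualifying subtrees (those with
#' no qualifying sub-branch) become the modules, which splits a branch as
#' deeply as the criteria allow. `deepSplit` maps to (maxCoreScatter,
#' minGap) as 0..4 -> maxCoreScatter (0.64, 0.73, 0.82, 0.91, 0.95) with
#' `minGap = (1 - maxCoreScatter) * 3/4`, so the default 1 gives
#' (0.73, 0.2025). Modules are labelled by decreasing size from a fixed
#' colour palette; everything else is `"grey"`.
#'
#' @param tom a TOM (typically the consensus) with site-id dimnames.
#' @param deepSplit split sensitivity 0..4 (default 1).
#' @param minModuleSize smallest allowed module (default 25).
#' @param cutHeightFrac cut as a fraction of the maximum merge height
#'   (default 0.99).
#' @return a \linkS4class{ModuleAssignment}.
#' @export
cutModules <- function(tom, deepSplit = 1L, minModuleSize = 25L,
                       cutHeightFrac = 0.99) {
    stopifnot(nrow(tom) >= 2L)
    if (nrow(tom) < minModuleSize)
        warning("fewer sites than minModuleSize: everything will be grey")
    par <- .deepSplitParams(deepSplit)
    d <- 1 - tom
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cutHeight <- cutHeightFrac * max(hc$height)
    refHeight <- stats::quantile(hc$height, 0.05, names = FALSE)
    maxAbsScatter <- refHeight + par$maxCoreScatter * (cutHeight - refHeight)
    minAbsGap <- par$minGap * (cutHeight - refHeight)
    st <- .nodeStats(hc)
    qual <- st$size >= minModuleSize &
        hc$height <= cutHeight &
        st$scatter <= maxAbsScatter &
        (st$attach - hc$height) >= minAbsGap
    ## keep minimal qualifying subtrees: drop nodes with a qualifying
    ## descendant (propagate bottom-up through the merge order)
    hasQualDesc <- logical(nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        for (child in hc$merge[i, ])
            if (child > 0L && (qual[child] || hasQualDesc[child]))
                hasQualDesc[i] <- TRUE
    }
    keep <- which(qual & !hasQualDesc)
    labels <- rep("grey", nrow(tom))
    names(labels) <- rownames(tom)
    if (length(keep)) {
        keep <- keep[order(-st$size[keep])]
        pal <- c(.modulePalette,
                 paste0("module", seq_len(max(0, length(keep) -
                                              length(.modulePalette)))))
        for (g in seq_along(keep))
            labels[.subtreeTips(hc, keep[g])] <- pal[g]
    }
    new("ModuleAssignment", labels = labels,
        minModuleSize = as.integer(minModuleSize))
}

#' Module eigengene and kME
#'
#' First principal component of the centered module submatrix. Scores
#' have zero mean across samples and the sign is oriented so the mean
#' correlation of module members with the scores (kME) is non-negative.
#' kME is returned for every CpG in the matrix, members and non-members.
#'
#' @param x complete \linkS4class{BetaMatrix}/matrix.
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @param module module label.
#' @return an \linkS4class{Eigengene}.
#' @export
moduleEigengene <- function(x, assignment, module) {
    b <- .betaOf(x)
    members <- names(assignment@labels)[assignment@labels == module]
    members <- intersect(members, rownames(b))
    if (!length(members)) stop("module ", module, " is empty in this matrix")
    sub <- b[members, , drop = FALSE]
    subC <- sub - rowMeans(sub)
    if (length(members) == 1L) {
        scores <- drop(subC)
    } else {
        sv <- svd(t(subC), nu = 1L, nv = 0L)
        scores <- drop(sv$u * sv$d[1L])
    }
    names(scores) <- colnames(b)
    kme <- suppressWarnings(
        as.vector(stats::cor(t(b), scores)))
    names(kme) <- rownames(b)
    if (mean(kme[members], na.rm = TRUE) < 0) {
        scores <- -scores
        kme <- -kme
    }
    new("Eigengene", module = module, scores = scores, kme = kme)
}

#' Prune weak module members by consensus kME
#'
#' For each CpG the consensus kME is the minimum across datasets of its
#' correlation with its own module's eigengene (computed per dataset).
#' Members below `minKme` are moved to grey; modules falling below the
#' size floor are dissolved; surviving modules are relabelled by
#' decreasing size from the fixed palette.
#'
#' @param xs a matrix/\linkS4class{BetaMatrix} or a list of them (one per
#'   dataset; consensus = minimum across the list).
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @param minKme kME floor (default 0.4).
#' @return the pruned \linkS4class{ModuleAssignment}.
#' @export
kmePrune <- function(xs, assignment, minKme = 0.4) {
    if (!is.list(xs)) xs <- list(xs)
    labels <- assignment@labels
    mods <- setdiff(unique(labels), "grey")
    for (m in mods) {
        members <- names(labels)[labels == m]
        consKme <- rep(Inf, length(members))
        for (x in xs) {
            eg <- moduleEigengene(x, assignment, m)
            consKme <- pmin(consKme, eg@kme[members])
        }
        labels[members[consKme < minKme]] <- "grey"
    }
    ## dissolve undersized modules, then relabel by decreasing size
    tab <- table(labels[labels != "grey"])
    for (m in names(tab)[tab < assignment@minModuleSize])
        labels[labels == m] <- "grey"
    tab <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
    newLab <- labels
    if (length(tab)) {
        pal <- c(.modulePalette,
                 paste0("module", seq_len(max(0, length(tab) -
                                              length(.modulePalette)))))
        for (i in seq_along(tab))
            newLab[labels == names(tab)[i]] <- pal[i]
    }
    new("ModuleAssignment", labels = newLab,
        minModuleSize = assignment@minModuleSize)
}

#' Module-specific PC clock
#'
#' Refits the PCA and the month rescaling restricted to one module's
#' CpGs, exactly as for the global clock.
#'
#' @param trainX complete training \linkS4class{BetaMatrix}/matrix.
#' @param trainAges training ages (months).
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @param module module label (size >= 2 required).
#' @param components PC indices (default 1).
#' @return a \linkS4class{PCClock}.
#' @export
moduleClock <- function(trainX, trainAges, assignment, module,
                        components = 1L) {
    b <- .betaOf(trainX)
    members <- intersect(names(assignment@labels)[assignment@labels == module],
                         rownames(b))
    if (length(members) < 2L) stop("module ", module, " has fewer than 2 sites")
    sub <- b[members, , drop = FALSE]
    pca <- fitPCA(sub, nComponents = max(components))
    fitPCClock(pca, sub, trainAges, components = components)
}
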