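## Cross-assembly CpG transfer: UCSC chain parsing, single-base liftover,
## site-set intersection, and refitting a PC clock on the conserved sites.

#' Read a UCSC chain file
#'
#' Parses the standard chain format (`chain score tName tSize tStrand
#' tStart tEnd qName qSize qStrand qStart qEnd id` headers followed by
#' `size dt dq` alignment lines). The first (t) assembly is the liftover
#' source, the second (q) the target; q coordinates are strand-local.
#' Gzipped files are accepted. Block arithmetic is validated against the
#' declared interval ends.
#'
#' @param path chain file.
#' @return a \linkS4class{ChainAlignment} with one row per ungapped block.
#' @export
readChain <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    hdr <- grep("^chain\\b", lines)
    if (!length(hdr)) stop("no chain records in ", path)
    ends <- c(hdr[-1L] - 1L, length(lines))
    out <- vector("list", length(hdr))
    for (i in seq_along(hdr)) {
        f <- strsplit(trimws(lines[hdr[i]]), "\\s+")[[1L]]
        if (length(f) < 12L) stop("malformed chain header at line ", hdr[i])
        score <- as.numeric(f[2L])
        srcChrom <- f[3L]; srcStart <- as.numeric(f[6L]); srcEnd <- as.numeric(f[7L])
        tgtChrom <- f[8L]; tgtSize <- as.numeric(f[9L]); tgtStrand <- f[10L]
        tgtStart <- as.numeric(f[11L]); tgtEnd <- as.numeric(f[12L])
        chainId <- if (length(f) >= 13L) f[13L] else as.character(i)
        body <- lines[(hdr[i] + 1L):ends[i]]
        body <- body[nzchar(trimws(body))]
        rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
        s <- srcStart; q <- tgtStart
        blk <- matrix(0, nrow = length(rows), ncol = 4L)
        for (r in seq_along(rows)) {
            v <- rows[[r]]
            size <- v[1L]
            blk[r, ] <- c(s, s + size, q, q + size)
            if (r < length(rows)) {
                if (length(v) < 3L)
                    stop("chain ", chainId, ": interior line lacks dt/dq")
                s <- s + size + v[2L]
                q <- q + size + v[3L]
            } else {
                s <- s + size; q <- q + size
            }
        }
        if (s != srcEnd || q != tgtEnd)
            stop("chain ", chainId, ": block arithmetic does not reach ",
                 "declared ends (", s, " vs ", srcEnd, "; ", q, " vs ",
                 tgtEnd, ")")
        out[[i]] <- data.frame(
            chainId = chainId, score = score, srcChrom = srcChrom,
            srcStart = blk[, 1L], srcEnd = blk[, 2L], tgtChrom = tgtChrom,
            tgtSize = tgtSize, tgtStrand = tgtStrand,
            tgtStart = blk[, 3L], tgtEnd = blk[, 4L], fileOrder = i)
    }
    new("ChainAlignment", blocks = do.call(rbind, out))
}

## 1-based site <-> 0-based chain conversion lives here, and only here.
.to0 <- function(pos1) pos1 - 1L
.to1 <- function(pos0) pos0 + 1L

#' Lift single-base sites through a chain alignment
#'
#' Each 1-based site is converted to 0-based, located in the ungapped
#' block of the highest-scoring chain containing it (ties broken by file
#' order), offset into the target, strand-flipped if the chain's target
#' strand is `-` (`tgt0 = tgtSizePlusEnd - offset - 1` on the plus
#' strand), and converted back to 1-based. Sites in chain gaps or outside
#' every chain are unmapped (`NA` target), which is a value, not an error.
#'
#' @param chain a \linkS4class{ChainAlignment}.
#' @param sites `GRanges` of width-1 sites or `"chrom:pos"` ids.
#' @return data.frame with `src`, `tgtChrom`, `tgtPos`, `tgt` (id or NA)
#'   and `chainScore`; one row per input site, input order preserved.
#' @export
liftoverSites <- function(chain, sites) {
    if (is.character(sites)) sites <- .parseSiteIds(sites)
    b <- chain@blocks
    blockGr <- GenomicRanges::GRanges(
        b$srcChrom, IRanges::IRanges(.to1(b$srcStart), b$srcEnd))
    hits <- GenomicRanges::findOverlaps(sites, blockGr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ## resolve multi-chain hits: best score, then first chain in file order
    if (length(qh)) {
        o <- order(qh, -b$score[sh], b$fileOrder[sh])
        keep <- o[!duplicated(qh[o])]
        qh <- qh[keep]; sh <- sh[keep]
    }
    n <- length(sites)
    tgtChrom <- rep(NA_character_, n)
    tgtPos <- rep(NA_integer_, n)
    score <- rep(NA_real_, n)
    if (length(qh)) {
        p0 <- .to0(GenomicRanges::start(sites)[qh])
        off <- p0 - b$srcStart[sh]
        plus <- b$tgtStrand[sh] == "+"
        t0 <- numeric(length(qh))
        t0[plus] <- b$tgtStart[sh][plus] + off[plus]
        if (any(!plus)) {
            ## strand-local block end on the plus strand:
            plusEnd <- b$tgtSize[sh][!plus] - b$tgtStart[sh][!plus]
            t0[!plus] <- plusEnd - off[!plus] - 1
        }
        tgtChrom[qh] <- b$tgtChrom[sh]
        tgtPos[qh] <- as.integer(.to1(t0))
        score[qh] <- b$score[sh]
    }
    data.frame(src = siteIdOf(sites), tgtChrom = tgtChrom, tgtPos = tgtPos,
               tgt = ifelse(is.na(tgtPos), NA_character_,
                            paste0(tgtChrom, ":", tgtPos)),
               chainScore = score, stringsAsFactors = FALSE)
}

#' Intersect lifted sites with another assembly's site set
#'
#' Keeps pairs whose mapped target exists in `otherSiteIds`. When two
#' sources collide on one target, the pair from the higher-scoring chain
#' wins (ties: first in input order); dropped collisions are reported.
#'
#' @param mapped output of [liftoverSites()].
#' @param otherSiteIds site ids (`"chrom:pos"`) of the other matrix.
#' @return data.frame with `src`, `tgt`, `chainScore`, ordered by source
#'   (chrom, pos).
#' @export
intersectMappedSites <- function(mapped, otherSiteIds) {
    m <- mapped[!is.na(mapped$tgt) & mapped$tgt %in% otherSiteIds,
                c("src", "tgt", "chainScore")]
    if (nrow(m)) {
        o <- order(m$tgt, -m$chainScore, seq_len(nrow(m)))
        dup <- duplicated(m$tgt[o])
        if (any(dup))
            message(sum(dup), " source sites dropped in target collisions")
        m <- m[o[!dup], ]
        gr <- .parseSiteIds(m$src)
        m <- m[.siteOrder(gr), ]
        rownames(m) <- NULL
    }
    m
}

#' Refit a PC clock on cross-species conserved sites
#'
#' Restricts the source training matrix to the paired source sites,
#' refits the PCA and the month rescaling there, and attaches the site
#' pairing so that [predictAge()] can consume target-assembly matrices
#' directly.
#'
#' @param srcTrainX source-species training \linkS4class{BetaMatrix}/matrix.
#' @param trainAges training ages (months).
#' @param pairing data.frame with `src`/`tgt` site ids
#'   (from [intersectMappedSites()]).
#' @param components PC indices for the clock (default 1).
#' @return a \linkS4class{PCClock} carrying the pairing.
#' @export
transferClock <- function(srcTrainX, trainAges, pairing, components = 1L) {
    if (nrow(pairing) < 2L) stop("pairing covers fewer than 2 sites")
    b <- .betaOf(srcTrainX)
    miss <- setdiff(pairing$src, rownames(b))
    if (length(miss))
        stop("source matrix lacks ", length(miss), " paired sites")
    b <- b[pairing$src, , drop = FALSE]
    pca <- fitPCA(b, nComponents = max(components))
    clock <- fitPCClock(pca, b, trainAges, components = components)
    clock@pairing <- pairing[match(pca@siteIds, pairing$src),
                             c("src", "tgt")]
    clock
}
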