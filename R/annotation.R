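## Genomic-context classification of CpGs (TSS distance, region category,
## CpG density) and region-set enrichment for modules.

#' Read gene models from GFF3/GTF
#'
#' Extracts gene and exon records (via rtracklayer). The transcription
#' start site is the 5' end of the gene on its strand.
#'
#' @param path GFF3/GTF file.
#' @return list with `genes` (GRanges, mcols `gene_id`) and `exons`
#'   (GRanges, mcols `gene_id`).
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path)
    idcol <- intersect(c("ID", "gene_id", "Name"),
                       colnames(S4Vectors::mcols(gr)))[1L]
    genes <- gr[gr$type == "gene"]
    exons <- gr[gr$type == "exon"]
    gid <- function(g) {
        v <- as.character(S4Vectors::mcols(g)[[idcol]])
        if (anyNA(v)) v[is.na(v)] <- paste0("gene", which(is.na(v)))
        v
    }
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gid(genes))
    par <- as.character(gr$Parent[gr$type == "exon"])
    S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
        gene_id = if (length(par) == length(exons)) par else gid(exons))
    list(genes = genes, exons = exons)
}

#' Read a BED region set
#'
#' BED intervals are 0-based half-open on disk; rtracklayer converts to
#' 1-based GRanges. Overlapping intervals are merged and the result is
#' sorted.
#'
#' @param path BED file.
#' @param name region-set name (default: file base name).
#' @return a GRanges with a `name` attribute in its metadata.
#' @export
readRegionSet <- function(path, name = sub("\\.bed(\\.gz)?$", "",
                                           basename(path))) {
    gr <- GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
    gr <- GenomicRanges::sort(gr)
    S4Vectors::metadata(gr)$name <- name
    gr
}

#' Catalogue CpG dinucleotides in a FASTA genome
#'
#' One site per "CG" occurrence on the forward strand, at the position of
#' the C.
#'
#' @param fasta FASTA path or a `DNAStringSet`.
#' @return sorted GRanges of width-1 CpG positions.
#' @export
scanCpGs <- function(fasta) {
    seqs <- if (is(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*", "", names(seqs))
    hits <- Biostrings::vmatchPattern("CG", seqs)
    grl <- lapply(names(seqs), function(nm) {
        st <- Biostrings::startIndex(hits)[[match(nm, names(seqs))]]
        if (is.null(st) || !length(st)) return(GenomicRanges::GRanges())
        GenomicRanges::GRanges(rep(nm, length(st)),
                               IRanges::IRanges(st, width = 1L),
                               strand = "+")
    })
    gr <- suppressWarnings(do.call(c, grl))
    gr[.siteOrder(gr)]
}

#' Local CpG density
#'
#' Number of catalogue CpGs within a `windowBp` window centered on each
#' site (`windowBp / 2` either side, inclusive, the site itself counted).
#'
#' @param sites query GRanges (or `"chrom:pos"` ids).
#' @param catalogue sorted GRanges of all CpG positions.
#' @param windowBp window span (default 100).
#' @return integer count per query site.
#' @export
cpgDensity <- function(sites, catalogue, windowBp = 100L) {
    if (is.character(sites)) sites <- .parseSiteIds(sites)
    half <- floor(windowBp / 2)
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(sites),
        IRanges::IRanges(pmax(1L, GenomicRanges::start(sites) - half),
                         GenomicRanges::start(sites) + half))
    GenomicRanges::countOverlaps(win, catalogue, ignore.strand = TRUE)
}

#' Signed distance to the nearest transcription start site
#'
#' Distance to the nearest gene's TSS, signed strand-aware: positive
#' means downstream of that gene's TSS (in the gene's direction of
#' transcription). Absolute distances are binned at decade edges
#' `<1e3, 1e3-1e4, 1e4-1e5, 1e5-1e6, >1e6`; sites on chromosomes without
#' genes are labelled `"no-gene"` with `NA` distance.
#'
#' @param sites query GRanges (or ids).
#' @param genes gene GRanges (stranded), e.g. `readGeneModels()$genes`.
#' @return data.frame with `site`, `distance`, `bin`.
#' @export
tssDistance <- function(sites, genes) {
    if (is.character(sites)) sites <- .parseSiteIds(sites)
    tssPos <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                     GenomicRanges::end(genes), GenomicRanges::start(genes))
    tssChrom <- as.character(GenomicRanges::seqnames(genes))
    tssStrand <- as.character(GenomicRanges::strand(genes))
    n <- length(sites)
    dist <- rep(NA_real_, n)
    sChrom <- as.character(GenomicRanges::seqnames(sites))
    sPos <- GenomicRanges::start(sites)
    for (ch in unique(sChrom)) {
        gi <- which(tssChrom == ch)
        si <- which(sChrom == ch)
        if (!length(gi)) next
        near <- vapply(sPos[si], function(p) gi[which.min(abs(tssPos[gi] - p))],
                       0L)
        raw <- sPos[si] - tssPos[near]
        dist[si] <- ifelse(tssStrand[near] == "-", -raw, raw)
    }
    ad <- abs(dist)
    bin <- cut(ad, c(-Inf, 1e3, 1e4, 1e5, 1e6, Inf), right = FALSE,
               labels = c("<1e3", "1e3-1e4", "1e4-1e5", "1e5-1e6", ">1e6"))
    bin <- as.character(bin)
    bin[is.na(dist)] <- "no-gene"
    data.frame(site = siteIdOf(sites), distance = dist, bin = bin,
               stringsAsFactors = FALSE)
}

#' Classify CpGs by genomic region
#'
#' Precedence: promoter (TSS +/- `flankBp`) > exon > intron (in the gene
#' body but not an exon) > TTS (transcription end +/- `flankBp`) >
#' intergenic. Every site receives exactly one label.
#'
#' @param sites query GRanges (or ids).
#' @param geneModels list with `genes` and `exons` (see [readGeneModels()]).
#' @param flankBp promoter/TTS flank (default 1000).
#' @return character vector of categories, one per site.
#' @export
classifyRegion <- function(sites, geneModels, flankBp = 1000L) {
    if (is.character(sites)) sites <- .parseSiteIds(sites)
    genes <- geneModels$genes
    exons <- geneModels$exons
    minus <- as.character(GenomicRanges::strand(genes)) == "-"
    tss <- ifelse(minus, GenomicRanges::end(genes), GenomicRanges::start(genes))
    tes <- ifelse(minus, GenomicRanges::start(genes), GenomicRanges::end(genes))
    mk <- function(center) GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes),
        IRanges::IRanges(pmax(1L, center - flankBp), center + flankBp))
    prom <- mk(tss)
    tts <- mk(tes)
    body <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                   IRanges::IRanges(GenomicRanges::start(genes),
                                                    GenomicRanges::end(genes)))
    ov <- function(set) GenomicRanges::countOverlaps(
        sites, set, ignore.strand = TRUE) > 0
    cat <- rep("intergenic", length(sites))
    cat[ov(tts)] <- "TTS"
    cat[ov(body)] <- "intron"
    cat[ov(exons)] <- "exon"
    cat[ov(prom)] <- "promoter"
    cat
}

#' Region-set enrichment of a module against a background
#'
#' For each region set, the 2x2 table crosses module membership (module
#' vs background-minus-module) with region overlap; the two-sided Fisher
#' exact p is computed and the fold is the ratio of in-region proportions
#' `(a/(a+b)) / (c/(c+d))`. q-values are Benjamini-Hochberg across the
#' supplied sets.
#'
#' @param moduleSites module CpGs (GRanges or ids); must be a subset of
#'   the background.
#' @param backgroundSites background CpGs (GRanges or ids).
#' @param regionSets named list of GRanges region sets.
#' @return data.frame with set, a, b, c, d, fold, p, q.
#' @export
regionEnrichment <- function(moduleSites, backgroundSites, regionSets) {
    if (is.character(moduleSites)) moduleSites <- .parseSiteIds(moduleSites)
    if (is.character(backgroundSites))
        backgroundSites <- .parseSiteIds(backgroundSites)
    if (!length(moduleSites)) stop("empty module")
    modIds <- siteIdOf(moduleSites)
    bgIds <- siteIdOf(backgroundSites)
    if (!all(modIds %in% bgIds))
        stop("module sites must be a subset of the background")
    inMod <- bgIds %in% modIds
    res <- lapply(names(regionSets), function(nm) {
        inReg <- GenomicRanges::countOverlaps(backgroundSites,
                                              regionSets[[nm]],
                                              ignore.strand = TRUE) > 0
        a <- sum(inMod & inReg); b <- sum(inMod & !inReg)
        c <- sum(!inMod & inReg); d <- sum(!inMod & !inReg)
        p <- stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                                alternative = "two.sided")$p.value
        pMod <- a / (a + b)
        pRest <- c / (c + d)
        data.frame(set = nm, a = a, b = b, c = c, d = d,
                   fold = if (pRest == 0) ifelse(pMod == 0, 1, Inf)
                          else pMod / pRest,
                   p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out
}
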