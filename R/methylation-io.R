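## Reading per-sample methylation call tables and assembling the cohort
## beta matrix with the coverage / completeness filters.

#' Read a per-sample methylation call table
#'
#' Two tab-separated dialects are supported. `cgmap`: chrom, nucleotide
#' (C = forward strand, G = reverse), 1-based position, context, dinucleotide,
#' beta fraction, methylated count, total count. `cov` (bismark coverage):
#' chrom, start, end (1-based), beta percentage, methylated count,
#' unmethylated count; percentages are divided by 100 and coverage is the
#' sum of the two counts. Gzipped files are accepted.
#'
#' Only CpG-context records are ingested from cgmap files; skipped CHG/CHH
#' rows are counted and reported via a message. Forward and reverse strand
#' CpG calls are kept as distinct sites (not collapsed).
#'
#' @param path file path.
#' @param dialect `"cgmap"` or `"cov"`.
#' @param sampleId sample identifier; defaults to the file base name.
#' @return a \linkS4class{MethylationCallSet}.
#' @export
readCalls <- function(path, dialect = c("cov", "cgmap"),
                      sampleId = sub("\\.(cov|cgmap)(\\.tsv)?(\\.gz)?$", "",
                                     basename(path))) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path)
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (dialect == "cov") {
        if (ncol(dt) != 6L)
            stop("cov dialect expects 6 columns, got ", ncol(dt))
        num <- lapply(dt[, 2:6], function(v) suppressWarnings(as.numeric(v)))
        bad <- which(Reduce(`|`, lapply(num, function(v) !is.finite(v))))
        if (length(bad))
            stop("malformed cov row at line ", bad[1], " of ", path)
        beta <- num[[3]] / 100
        cov <- as.integer(num[[4]] + num[[5]])
        gr <- GenomicRanges::GRanges(
            dt[[1]], IRanges::IRanges(as.integer(dt[[2]]), width = 1L),
            strand = "*")
    } else {
        if (ncol(dt) != 8L)
            stop("cgmap dialect expects 8 columns, got ", ncol(dt))
        keep <- dt[[4]] == "CG" | dt[[5]] == "CG"
        nskip <- sum(!keep)
        if (nskip)
            message(nskip, " non-CpG context rows skipped in ", basename(path))
        dt <- dt[keep, ]
        b6 <- suppressWarnings(as.numeric(dt[[6]]))
        b8 <- suppressWarnings(as.numeric(dt[[8]]))
        bad <- which(!is.finite(b6) | !is.finite(b8))
        if (length(bad))
            stop("malformed cgmap row at line ", bad[1], " of ", path)
        beta <- b6
        cov <- as.integer(b8)
        gr <- GenomicRanges::GRanges(
            dt[[1]], IRanges::IRanges(as.integer(dt[[3]]), width = 1L),
            strand = ifelse(dt[[2]] == "G", "-", "+"))
    }
    if (any(beta < -1e-9 | beta > 1 + 1e-9, na.rm = TRUE))
        stop("beta outside [0,1] after normalization in ", path)
    S4Vectors::mcols(gr)$beta <- pmin(pmax(beta, 0), 1)
    S4Vectors::mcols(gr)$coverage <- cov
    MethylationCallSet(sampleId, gr)
}

#' Assemble a cohort BetaMatrix from call sets
#'
#' Takes the union of sites across samples. An entry is missing (`NA`)
#' when the sample has no record at the site or when its coverage is not
#' strictly greater than `minCoverage` — i.e. sites covered at exactly
#' 10x are masked under the default, matching a "greater than 10x" rule.
#'
#' @param callsets list of \linkS4class{MethylationCallSet}.
#' @param minCoverage strict lower coverage bound (default 10).
#' @param sampleData optional per-sample metadata (see [BetaMatrix()]).
#' @return a \linkS4class{BetaMatrix}.
#' @export
assembleMatrix <- function(callsets, minCoverage = 10L, sampleData = NULL) {
    stopifnot(length(callsets) >= 1L)
    ids <- vapply(callsets, function(cs) cs@sampleId, "")
    if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    allIds <- unique(unlist(lapply(callsets, function(cs) siteIdOf(cs@calls))))
    sites <- .parseSiteIds(allIds)
    o <- .siteOrder(sites)
    sites <- sites[o]
    allIds <- allIds[o]
    beta <- matrix(NA_real_, nrow = length(allIds), ncol = length(ids),
                   dimnames = list(allIds, ids))
    for (k in seq_along(callsets)) {
        cs <- callsets[[k]]
        mc <- S4Vectors::mcols(cs@calls)
        keep <- mc$coverage > minCoverage
        idx <- match(siteIdOf(cs@calls)[keep], allIds)
        beta[idx, k] <- mc$beta[keep]
    }
    BetaMatrix(beta, sites, sampleData = sampleData)
}

#' Keep sites observed in a sufficient fraction of samples
#'
#' Retains sites whose present-value count is at least
#' `ceiling(minFraction * n_samples)` ("at least 80% of the samples" is a
#' lower bound, hence the ceiling). Site order is preserved.
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @param minFraction required fraction of samples with a present value.
#' @return the filtered \linkS4class{BetaMatrix}.
#' @export
filterSites <- function(x, minFraction = 0.8) {
    stopifnot(minFraction > 0, minFraction <= 1)
    b <- betaValues(x)
    need <- ceiling(minFraction * ncol(b))
    keep <- rowSums(!is.na(b)) >= need
    if (!any(keep)) warning("no sites survive the completeness filter")
    x[keep, ]
}

#' Write / read a BetaMatrix as TSV
#'
#' Rows are `"chrom:pos"` site ids, columns are samples; missing entries
#' are empty cells. Values round-trip to 6 decimals.
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBetaMatrix <- function(x, path) {
    b <- betaValues(x)
    dt <- data.table::data.table(site = rownames(b))
    for (j in colnames(b)) dt[[j]] <- round(b[, j], 6)
    data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
    invisible(path)
}

#' @rdname writeBetaMatrix
#' @param sampleData optional per-sample metadata for the read side.
#' @export
readBetaMatrix <- function(path, sampleData = NULL) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
    b <- as.matrix(dt[, -1, with = FALSE])
    rownames(b) <- dt[[1]]
    BetaMatrix(b, .parseSiteIds(dt[[1]]), sampleData = sampleData)
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns `sample_id`, `species`, `age_months`,
#' `diet`, `cr_duration_months`, `tissue` (and optionally `split`).
#' Validates that ages are positive and that `cr_duration_months` is zero
#' for ad-libitum (`AL`) animals.
#'
#' @param path TSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
readSampleTable <- function(path) {
    df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
    need <- c("sample_id", "species", "age_months", "diet",
              "cr_duration_months", "tissue")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("sample table lacks columns: ",
                           paste(miss, collapse = ", "))
    if (any(df$age_months <= 0)) stop("age_months must be positive")
    if (any(df$diet == "AL" & df$cr_duration_months != 0))
        stop("cr_duration_months must be 0 for AL animals")
    rownames(df) <- df$sample_id
    df
}
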