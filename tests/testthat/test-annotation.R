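makeGff <- function(path) {
    writeLines(c(
        "##gff-version 3",
        "chr1\ttest\tgene\t10000\t20000\t.\t+\t.\tID=gA",
        "chr1\ttest\tgene\t50000\t70000\t.\t-\t.\tID=gB",
        "chr2\ttest\tgene\t5000\t9000\t.\t+\t.\tID=gC",
        "chr1\ttest\texon\t10000\t10400\t.\t+\t.\tID=gA.1;Parent=gA",
        "chr1\ttest\texon\t15000\t15500\t.\t+\t.\tID=gA.2;Parent=gA",
        "chr1\ttest\texon\t69000\t70000\t.\t-\t.\tID=gB.1;Parent=gB",
        "chr2\ttest\texon\t5000\t5200\t.\t+\t.\tID=gC.1;Parent=gC"), path)
    path
}

test_that("CpG scanning finds CG dinucleotides at the C position", {
    ss <- Biostrings::DNAStringSet(c(s1 = "ACGCGT", s2 = "AAATTT"))
    gr <- scanCpGs(ss)
    expect_equal(siteIdOf(gr), c("s1:2", "s1:4"))
    # random sequence against a string-scan oracle
    set.seed(71)
    seq1 <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
    got <- GenomicRanges::start(scanCpGs(
        Biostrings::DNAStringSet(c(chrZ = seq1))))
    oracle <- gregexpr("(?=CG)", seq1, perl = TRUE)[[1]]
    expect_equal(got, as.integer(oracle))
})

test_that("CpG density counts a centered window including the site", {
    cat <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(100L, 120L, 160L),
                                                   width = 1L))
    # isolated site: itself only
    expect_equal(cpgDensity("chr1:100", cat[1]), 1L)
    # window 70..170 around 120 catches all three
    expect_equal(cpgDensity("chr1:120", cat), 3L)
    expect_equal(cpgDensity("chr1:160", cat), 2L)   # 110..210
    # chromosome start does not underflow
    cat2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2L, 30L),
                                                            width = 1L))
    expect_equal(cpgDensity("chr1:2", cat2), 2L)
    # translation invariance
    shift <- 5000L
    cat3 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(100L, 120L, 160L) +
                                                    shift, width = 1L))
    expect_equal(cpgDensity(paste0("chr1:", 120 + shift), cat3), 3L)
})

test_that("TSS distances are strand-aware with decade bins", {
    p <- withr::local_tempfile(fileext = ".gff3")
    gm <- readGeneModels(makeGff(p))
    # + strand gene gA: TSS at 10000
    d <- tssDistance("chr1:10000", gm$genes)
    expect_equal(d$distance, 0)
    expect_equal(d$bin, "<1e3")
    d2 <- tssDistance("chr1:24000", gm$genes)   # 14000 downstream of gA
    expect_equal(d2$distance, 14000)
    expect_equal(d2$bin, "1e4-1e5")
    # - strand gene gB: TSS at 70000; site at 69000 is 1000 downstream
    d3 <- tssDistance("chr1:69000", gm$genes)
    expect_equal(d3$distance, 1000)
    expect_equal(d3$bin, "1e3-1e4")
    # upstream of a + strand TSS is negative
    d4 <- tssDistance("chr2:4500", gm$genes)
    expect_equal(d4$distance, -500)
    # no gene on the chromosome
    d5 <- tssDistance("chr9:100", gm$genes)
    expect_true(is.na(d5$distance))
    expect_equal(d5$bin, "no-gene")
})

test_that("region classification follows the stated precedence", {
    p <- withr::local_tempfile(fileext = ".gff3")
    gm <- readGeneModels(makeGff(p))
    # 500 bp upstream of gA's TSS -> promoter
    expect_equal(classifyRegion("chr1:9500", gm), "promoter")
    # inside gA exon 2 but far from TSS -> exon
    expect_equal(classifyRegion("chr1:15200", gm), "exon")
    # exon within 1 kb of TSS -> promoter wins
    expect_equal(classifyRegion("chr1:10200", gm), "promoter")
    # gene body, between exons -> intron
    expect_equal(classifyRegion("chr1:12000", gm), "intron")
    # within 1 kb of gA's transcription end (20000), outside the body
    expect_equal(classifyRegion("chr1:20500", gm), "TTS")
    # far from everything -> intergenic
    expect_equal(classifyRegion("chr1:40000", gm), "intergenic")
    # every site receives exactly one category
    set.seed(72)
    sites <- paste0("chr1:", sample(1:80000, 200))
    cats <- classifyRegion(sites, gm)
    expect_length(cats, 200L)
    expect_true(all(cats %in% c("promoter", "exon", "intron", "TTS",
                                "intergenic")))
    # hand classification of a 20-site fixture
    fix <- paste0("chr1:", c(9200, 9950, 10100, 10450, 12500, 14800, 15100,
                             15600, 19500, 20100, 20900, 21500, 30000,
                             49200, 50500, 60000, 69500, 70500, 71500, 80000))
    # chr1:50500 sits in gB's body within 1 kb of its TES: intron wins
    # over TTS under the stated precedence
    hand <- c("promoter", "promoter", "promoter", "promoter", "intron",
              "intron", "exon", "intron", "intron", "TTS", "TTS",
              "intergenic", "intergenic", "TTS", "intron", "intron",
              "promoter", "promoter", "intergenic", "intergenic")
    expect_equal(classifyRegion(fix, gm), hand)
})

test_that("BED region sets load 1-based, merged and sorted", {
    p <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t99\t200", "chr1\t150\t300", "chr1\t500\t600"), p)
    gr <- readRegionSet(p)
    expect_equal(length(gr), 2L)
    expect_equal(GenomicRanges::start(gr), c(100L, 501L))
    expect_equal(GenomicRanges::end(gr), c(300L, 600L))
})

test_that("enrichment tables match the hypergeometric enumeration", {
    # module of 10 vs background of 110, one region set
    bg <- paste0("chr1:", seq(1000, 110000, by = 1000))
    mod <- bg[1:10]
    regionCover <- function(ids) {
        gr <- methclock:::.parseSiteIds(ids)
        GenomicRanges::reduce(GenomicRanges::GRanges(
            GenomicRanges::seqnames(gr),
            IRanges::IRanges(GenomicRanges::start(gr) - 10,
                             GenomicRanges::start(gr) + 10)))
    }
    # (a,b,c,d) = (8,2,10,90)
    sets <- list(mark = regionCover(c(mod[1:8], bg[11:20])))
    er <- regionEnrichment(mod, bg, sets)
    expect_equal(c(er$a, er$b, er$c, er$d), c(8, 2, 10, 90))
    expect_equal(er$p, fisherOracle(8, 2, 10, 90), tolerance = 1e-12)
    expect_equal(er$fold, (8 / 10) / (10 / 100))
    # balanced proportions: fold 1, p 1
    sets2 <- list(flat = regionCover(c(mod[1:5], bg[11:60])))
    er2 <- regionEnrichment(mod, bg, sets2)
    expect_equal(er2$fold, 1)
    expect_equal(er2$p, 1)
    # strong-contrast fixture in the published ballpark: 98% vs ~13%
    bgBig <- paste0("chr2:", seq(1000, 600000, by = 1000))
    modBig <- bgBig[1:100]
    inReg <- c(modBig[1:98], bgBig[101:166])   # 98/100 vs 66/500 = 13.2%
    er3 <- regionEnrichment(modBig, bgBig, list(k9 = regionCover(inReg)))
    expect_equal(er3$fold, (98 / 100) / (66 / 500), tolerance = 1e-12)
    expect_gt(er3$fold, 7)
    expect_lt(er3$fold, 7.8)
    # BH adjustment across sets and the subset precondition
    erAll <- regionEnrichment(mod, bg, c(sets, sets2))
    expect_equal(erAll$q, p.adjust(erAll$p, "BH"))
    expect_true(all(erAll$q >= erAll$p))
    expect_error(regionEnrichment("chr9:1", bg, sets), "subset")
    expect_error(regionEnrichment(character(0), bg, sets), "empty")
})

test_that("Fisher p equals the enumeration oracle across random tables", {
    set.seed(73)
    for (i in 1:25) {
        n <- sample(20:200, 1)
        m <- sample(5:(n - 5), 1)
        reg <- sample(1:(n - 1), 1)
        a <- max(0, reg - (n - m)):min(m, reg)
        a <- sample(a, 1)
        tab <- matrix(c(a, m - a, reg - a, n - m - reg + a), 2, byrow = TRUE)
        if (any(tab < 0)) next
        expect_equal(stats::fisher.test(tab)$p.value,
                     fisherOracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                     tolerance = 1e-9)
    }
})
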