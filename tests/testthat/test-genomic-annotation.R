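si <- GenomeInfoDb::Seqinfo("chr1", 100000L)

.mkGene <- function(start, end, strand, name = "g1", exons = NULL, si. = si) {
    g <- GRanges("chr1", IRanges(start, end), strand = strand, seqinfo = si.)
    if (is.null(exons)) exons <- IRanges(1L, end - start + 1L)
    mcols(g)$name <- name
    mcols(g)$blocks <- IRanges::IRangesList(list(exons))
    g
}

test_that("promoter windows are strand-aware and clipped", {
    # + strand, TSS at 0-based 10000 => 0-based [9000, 10500)
    g <- .mkGene(10001, 20000, "+")
    p <- promoterInterval(g)
    expect_equal(c(start(p), end(p)), c(9001L, 10500L))
    # - strand, TSS at 0-based txEnd 20000 => [19500, 21000)
    gm <- .mkGene(8001, 20000, "-")
    pm <- promoterInterval(gm)
    expect_equal(c(start(pm), end(pm)), c(19501L, 21000L))
    # clipping at the chromosome start: TSS at 0-based 300 => [0, 800)
    gc <- .mkGene(301, 5000, "+")
    pc <- promoterInterval(gc)
    expect_equal(c(start(pc), end(pc)), c(1L, 800L))
    # the window always contains the TSS after clipping
    expect_true(start(pc) <= 301 && end(pc) >= 301)
})

test_that("3' windows are symmetric around the TTS and clipped", {
    # + strand, TTS at 0-based 50000 => [49000, 51000)
    g <- .mkGene(40001, 50000, "+")
    t3 <- threePrimeInterval(g)
    expect_equal(c(start(t3), end(t3)), c(49001L, 51000L))
    # - strand, TTS at 0-based txStart 8000 => [7000, 9000)
    gm <- .mkGene(8001, 20000, "-")
    t3m <- threePrimeInterval(gm)
    expect_equal(c(start(t3m), end(t3m)), c(7001L, 9000L))
    # TTS at 0-based 500 => clipped [0, 1500)
    ge <- .mkGene(101, 500, "+")
    t3e <- threePrimeInterval(ge)
    expect_equal(c(start(t3e), end(t3e)), c(1L, 1500L))
})

test_that("feature priority resolves pooled overlaps", {
    # gene1 with promoter at [9000,10500); gene2 intronic elsewhere
    g1 <- .mkGene(10001, 20000, "+", "g1",
                  IRanges(c(1, 8001), c(500, 10000)))
    g2 <- .mkGene(9001, 15000, "+", "g2",
                  IRanges(c(1, 5901), c(100, 6000)))
    genes <- c(g1, g2)
    # DMR overlapping g1's promoter and g2's intron: promoter wins
    d <- GRanges("chr1", IRanges(9501, 9600), seqinfo = si)
    fc <- classifyFeature(d, genes)
    expect_equal(as.character(fc$category), "promoter")
    # DMR in open space: intergenic
    d2 <- GRanges("chr1", IRanges(90001, 90100), seqinfo = si)
    expect_equal(as.character(classifyFeature(d2, genes)$category),
                 "intergenic")
    # no genes at all: everything intergenic
    expect_equal(as.character(classifyFeature(d, genes[0])$category),
                 "intergenic")
})

test_that("feature classification equals the per-base oracle", {
    set.seed(77)
    for (rep in 1:6) {
        nG <- sample(2:4, 1)
        genome <- makeToyGenome(1, 2e5)
        ann <- makeAnnotations(genome, nG, 0, seed = rep,
                               geneWidthRange = c(8e3, 3e4))
        dmrs <- GRanges("chr1",
                        IRanges(sample.int(195000, 150), width = 200),
                        seqinfo = genome)
        got <- classifyFeature(dmrs, ann$genes)
        for (i in seq_along(dmrs)) {
            expect_equal(as.character(got$category[i]),
                         featureOracle(dmrs[i], ann$genes),
                         label = sprintf("rep %d dmr %d", rep, i))
        }
    }
})

test_that("CGI context bands follow edge distances", {
    isl <- GRanges("chr1", IRanges(50001, 51000), seqinfo = si)
    mk <- function(s, e) GRanges("chr1", IRanges(s, e), seqinfo = si)
    expect_equal(as.character(classifyCgiContext(mk(50500, 50600), isl)$context),
                 "island")
    # 1500 bp away: shore
    cc <- classifyCgiContext(mk(52501, 52600), isl)
    expect_equal(as.character(cc$context), "shore")
    expect_equal(cc$distance, 1500)
    # exactly 2000: still shore; 2001: shelf
    expect_equal(as.character(classifyCgiContext(mk(53001, 53100), isl)$context),
                 "shore")
    expect_equal(as.character(classifyCgiContext(mk(53002, 53100), isl)$context),
                 "shelf")
    # 4500 away: open sea
    expect_equal(as.character(classifyCgiContext(mk(55501, 55600), isl)$context),
                 "open_sea")
    # empty island set: open sea at infinite distance
    cc0 <- classifyCgiContext(mk(1, 100), isl[0])
    expect_equal(as.character(cc0$context), "open_sea")
    expect_equal(cc0$distance, Inf)
})

test_that("CGI distances equal the brute-force minimum over islands", {
    set.seed(88)
    isl <- GRanges("chr1", IRanges(sort(sample.int(90000, 12)) * 1L,
                                   width = sample(200:900, 12)),
                   seqinfo = si)
    isl <- reduce(isl)
    dmrs <- GRanges("chr1", IRanges(sample.int(95000, 200), width = 150),
                    seqinfo = si)
    got <- classifyCgiContext(dmrs, isl)
    for (i in seq_along(dmrs))
        expect_equal(got$distance[i], cgiDistanceOracle(dmrs[i], isl))
    # exactly one label per DMR
    expect_false(any(is.na(got$context)))
})

test_that("context proportions sum to 100 within each direction", {
    calls <- c("promoter", "promoter", "intron", "intergenic")
    dir <- c("01", "01", "01", "01")
    pr <- contextProportions(calls, dir)
    expect_equal(pr$percent[pr$category == "promoter"], 50)
    expect_equal(sum(pr$percent), 100)
    # single DMR: 100 % in its category
    pr1 <- contextProportions("exon", "10")
    expect_equal(pr1$percent, 100)
    # two directions partition separately
    pr2 <- contextProportions(c("exon", "intron", "intron"),
                              c("01", "10", "10"))
    for (d in c("01", "10"))
        expect_equal(sum(pr2$percent[pr2$direction == d]), 100,
                     tolerance = 0.1)
    expect_equal(nrow(contextProportions(character(0), character(0))), 0L)
})
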