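test_that("toy genomes have the requested shape", {
    g <- makeToyGenome(1, 1000)
    expect_equal(unname(GenomeInfoDb::seqlengths(g)), 1000L)
    g2 <- makeToyGenome(2, 5e6)
    expect_equal(sum(as.numeric(GenomeInfoDb::seqlengths(g2))), 1e7)
    expect_error(makeToyGenome(0, 1000), "positive")
    expect_error(makeToyGenome(1, -5), "positive")
})

test_that("annotations are reproducible, non-overlapping and BED12-valid", {
    genome <- makeToyGenome(2, 5e6)
    a1 <- makeAnnotations(genome, 50, 30, seed = 3)
    a2 <- makeAnnotations(genome, 50, 30, seed = 3)
    expect_identical(a1$genes, a2$genes)
    expect_identical(a1$islands, a2$islands)
    expect_equal(length(a1$genes), 50L)
    expect_true(all(countOverlaps(a1$genes, a1$genes,
                                  ignore.strand = TRUE) == 1L))
    expect_true(all(countOverlaps(a1$islands, a1$islands) == 1L))
    # exon blocks: sorted, non-overlapping, spanning the gene body
    for (i in seq_along(a1$genes)) {
        bl <- mcols(a1$genes)$blocks[[i]]
        expect_equal(start(bl)[1], 1L)
        expect_equal(max(end(bl)), width(a1$genes)[i])
        if (length(bl) > 1) {
            expect_true(all(diff(start(bl)) > 0))
            expect_true(all(start(bl)[-1] > end(bl)[-length(bl)]))
        }
    }
    # empty gene set is allowed and annotates everything intergenic
    a0 <- makeAnnotations(genome, 0, 0, fracIslandsInPromoters = 0,
                          seed = 1)
    expect_equal(length(a0$genes), 0L)
    d <- GRanges("chr1", IRanges(5000, 5100))
    expect_equal(as.character(classifyFeature(d, a0$genes)$category),
                 "intergenic")
})

test_that("island placement honours the promoter fraction", {
    genome <- makeToyGenome(2, 5e6)
    ann <- makeAnnotations(genome, 40, 30, fracIslandsInPromoters = 1,
                           seed = 5)
    prom <- promoterInterval(ann$genes)
    expect_true(all(overlapsAny(ann$islands, prom, ignore.strand = TRUE)))
})

test_that("planted truth satisfies its structural contract", {
    genome <- makeToyGenome(2, 5e6)
    ann <- makeAnnotations(genome, 50, 0, seed = 2)
    cfg <- truthConfig(nSharp01 = 30, nSharp10 = 30, nQuantitative = 10,
                       nShared = 12, nInverseGenes = 8)
    tr <- plantTruth(genome, ann$genes, cfg, nSamples = 6, seed = 11)
    r <- truthRegions(tr)
    kinds <- table(mcols(r)$kind)
    expect_equal(unname(kinds[c("sharp01", "sharp10", "quantitative",
                                "shared_methylated")]),
                 c(30L, 30L, 10L, 12L), ignore_attr = TRUE)
    expect_true(all(countOverlaps(r, r, ignore.strand = TRUE) == 1L))
    expect_true(all(truthSizeFactors(tr) > 0))
    # reproducibility
    tr2 <- plantTruth(genome, ann$genes, cfg, nSamples = 6, seed = 11)
    expect_identical(granges(truthRegions(tr2)), granges(r))

    # every inverse gene has exactly one opposite-direction sharp promoter
    # region, and its planted DE direction is inverse
    prom <- promoterInterval(ann$genes)
    ids <- mcols(ann$genes)$name
    de <- truthDETable(tr)
    for (g in truthInverseGenes(tr)) {
        p <- prom[ids == g]
        hit <- r[overlapsAny(r, p, ignore.strand = TRUE)]
        expect_equal(length(hit), 1L)
        expect_true(mcols(hit)$kind %in% c("sharp01", "sharp10"))
        fold <- de$foldChange[de$gene == g]
        if (mcols(hit)$kind == "sharp01") expect_lt(fold, 1)
        else expect_gt(fold, 1)
    }
    # no planted regions at all is a valid configuration
    tr0 <- plantTruth(genome, ann$genes,
                      truthConfig(nSharp01 = 0, nSharp10 = 0, nShared = 0,
                                  nInverseGenes = 0),
                      nSamples = 6, seed = 1)
    expect_equal(length(truthRegions(tr0)), 0L)
})

test_that("simulated counts follow the planted rates", {
    genome <- makeToyGenome(1, 5e6)   # 100k windows
    ann <- makeAnnotations(genome, 20, 0, seed = 2)
    cfg <- truthConfig(nSharp01 = 15, nSharp10 = 15, nShared = 5,
                       nInverseGenes = 5)
    tr <- plantTruth(genome, ann$genes, cfg, nSamples = 6, seed = 3)
    design <- sampleDesign(3, 3)
    x <- simulateCounts(genome, tr, design, seed = 4)
    counts <- assay(x, "counts")
    sf <- truthSizeFactors(tr)
    grid <- rowRanges(x)
    inRegion <- overlapsAny(grid, truthRegions(tr), ignore.strand = TRUE)
    # background windows: empirical mean within 3 SE of sf * 0.3
    for (s in c(1, 4)) {
        bg <- counts[!inRegion, s]
        mu <- sf[s] * 0.3
        se <- sqrt(mu / length(bg))
        expect_lt(abs(mean(bg) - mu), 3 * se)
    }
    # group A samples on sharp01 regions stay at background rate
    r01 <- truthRegions(tr)[mcols(truthRegions(tr))$kind == "sharp01"]
    w01 <- which(overlapsAny(grid, r01, ignore.strand = TRUE))
    for (s in 1:3) {
        mu <- sf[s] * 0.3
        se <- sqrt(mu / length(w01))
        expect_lt(abs(mean(counts[w01, s]) - mu), 4 * se + 0.05)
    }
    # group B samples on sharp01 regions are at the methylated rate
    for (s in 4:6) {
        mu <- sf[s] * 25
        se <- sqrt(mu / length(w01))
        expect_lt(abs(mean(counts[w01, s]) - mu), 4 * se)
    }
    # determinism
    x2 <- simulateCounts(genome, tr, design, seed = 4)
    expect_identical(assay(x2, "counts"), counts)
    # all-zero rates give all-zero counts
    cfg0 <- truthConfig(nSharp01 = 0, nSharp10 = 0, nShared = 0,
                        nInverseGenes = 0, backgroundRate = 0)
    tr0 <- plantTruth(genome, ann$genes, cfg0, nSamples = 4, seed = 1)
    x0 <- simulateCounts(genome, tr0, sampleDesign(2, 2), seed = 1)
    expect_true(all(assay(x0, "counts") == 0L))
    expect_error(simulateCounts(genome, tr0, sampleDesign(1, 3), seed = 1),
                 "2 samples")
})

test_that("simulated expression carries planted folds and clean nulls", {
    genome <- makeToyGenome(2, 5e6)
    ann <- makeAnnotations(genome, 40, 0, seed = 6)
    tr <- plantTruth(genome, ann$genes,
                     truthConfig(nSharp01 = 10, nSharp10 = 10,
                                 nInverseGenes = 6, nShared = 0),
                     nSamples = 6, seed = 7)
    # overwrite two planted folds with reference magnitudes to check the
    # table carries them verbatim
    tr@deTable$foldChange[1:2] <- c(0.19, 6.44)
    expr <- simulateExpression(ann$genes, tr, seed = 8)
    expect_equal(nrow(expr), 40L)
    for (i in 1:2) {
        g <- tr@deTable$gene[i]
        expect_equal(expr$fold_change[expr$gene == g],
                     tr@deTable$foldChange[i])
        expect_lt(expr$padj[expr$gene == g], 0.05)
    }
    nonDe <- setdiff(expr$gene, tr@deTable$gene)
    expect_true(all(expr$padj[expr$gene %in% nonDe] >= 0.05))
    expect_true(all(abs(log(expr$fold_change[expr$gene %in% nonDe])) < 0.3))
    # with no planted DE genes no row is significant
    tr0 <- plantTruth(genome, ann$genes,
                      truthConfig(nSharp01 = 5, nSharp10 = 5,
                                  nInverseGenes = 0, nShared = 0),
                      nSamples = 6, seed = 9)
    tr0@deTable <- tr0@deTable[0, ]
    expr0 <- simulateExpression(ann$genes, tr0, seed = 10)
    expect_false(any(expr0$padj < 0.05))
    # unknown planted gene id is rejected
    trBad <- tr
    trBad@deTable$gene[1] <- "nope"
    expect_error(simulateExpression(ann$genes, trBad, seed = 1),
                 "not in the gene set")
})
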