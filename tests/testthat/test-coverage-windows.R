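si <- GenomeInfoDb::Seqinfo(c("chr1", "chr2"), c(10000L, 5000L))

test_that("fragment extension anchors at the 5' end and clips to bounds", {
    fr <- GRanges(c("chr1", "chr1", "chr1"),
                  IRanges(c(101, 251, 101), c(150, 300, 150)),
                  strand = c("+", "-", "+"), seqinfo = si)
    out <- extendFragments(fr, 120)
    expect_equal(start(out), c(101, 181, 101))
    expect_equal(end(out), c(220, 300, 150 + 70))
    # length == target leaves fragments unchanged
    out50 <- extendFragments(fr[1], 50)
    expect_equal(ranges(out50), ranges(fr[1]))
    # clipping at chromosome edges
    edge <- GRanges("chr2", IRanges(4950, 4999), strand = "+", seqinfo = si)
    expect_equal(end(extendFragments(edge, 200)), 5000)
    low <- GRanges("chr1", IRanges(1, 50), strand = "-", seqinfo = si)
    expect_equal(start(extendFragments(low, 200)), 1)
    # unstranded fragments of a different length are ambiguous
    un <- GRanges("chr1", IRanges(1, 50), strand = "*", seqinfo = si)
    expect_error(extendFragments(un, 120), "ambiguous")
    expect_silent(extendFragments(un, 50))
})

test_that("window tiling covers each chromosome with a truncated tail", {
    g <- tileWindows(c(chrA = 160L), 50)
    expect_equal(start(g), c(1, 51, 101, 151))
    expect_equal(end(g), c(50, 100, 150, 160))
    expect_equal(length(tileWindows(c(chrA = 100L), 50)), 2L)
    short <- tileWindows(c(chrA = 49L), 50)
    expect_equal(width(short), 49L)
    # union covers the genome exactly, no overlap
    g2 <- tileWindows(si, 50)
    expect_equal(sum(width(g2)), sum(GenomeInfoDb::seqlengths(si)))
    expect_true(all(countOverlaps(g2, g2) == 1L))
})

test_that("coverage counting matches a naive per-base pileup", {
    # hand-built rounding cases on one 50-bp window
    g1 <- tileWindows(c(chrA = 50L), 50)
    siA <- GenomeInfoDb::Seqinfo("chrA", 50L)
    full <- GRanges("chrA", IRanges(1, 50), strand = "+", seqinfo = siA)
    half <- GRanges("chrA", IRanges(1, 25), strand = "+", seqinfo = siA)
    expect_equal(assay(countCoverage(g1, list(s = full)), "counts")[1, 1], 1L)
    # 25/50 = 0.5 rounds away from zero to 1
    expect_equal(assay(countCoverage(g1, list(s = half)), "counts")[1, 1], 1L)
    # 3 full + 1 half = 3.5 -> 4
    fr <- c(full, full, full, half)
    expect_equal(assay(countCoverage(g1, list(s = fr)), "counts")[1, 1], 4L)

    # random fixtures vs the per-base oracle, incl. a truncated window
    set.seed(42)
    siR <- GenomeInfoDb::Seqinfo(c("chr1", "chr2"), c(2130L, 990L))
    grid <- tileWindows(siR, 50)
    for (rep in 1:5) {
        n <- 120
        chr <- sample(c("chr1", "chr2"), n, replace = TRUE, prob = c(2, 1))
        len <- GenomeInfoDb::seqlengths(siR)[chr]
        st <- vapply(len, function(L) sample.int(L - 60L, 1L), integer(1))
        fr <- GRanges(chr, IRanges(st, width = sample(20:60, n, TRUE)),
                      strand = sample(c("+", "-"), n, TRUE), seqinfo = siR)
        fr <- extendFragments(fr, 55)
        got <- assay(countCoverage(grid, list(s = fr)), "counts")[, 1]
        expect_equal(got, pileupOracle(grid, fr))
    }
    # unknown chromosome is an error
    badsi <- GenomeInfoDb::Seqinfo(c("chr1", "chrX"), c(2130L, 500L))
    bad <- GRanges("chrX", IRanges(1, 50), strand = "+", seqinfo = badsi)
    expect_error(countCoverage(grid, list(s = bad)), "unknown chromosome")
})

test_that("coverage totals are conserved up to rounding", {
    set.seed(11)
    siR <- GenomeInfoDb::Seqinfo("chr1", 5000L)
    grid <- tileWindows(siR, 50)
    fr <- GRanges("chr1", IRanges(sample.int(4800, 200), width = 120),
                  strand = "+", seqinfo = siR)
    fr <- trim(fr)
    counts <- assay(countCoverage(grid, list(s = fr)), "counts")[, 1]
    expect_lt(abs(sum(counts * width(grid)) - sum(width(fr))),
              length(grid) / 2 * 50 + 1)
})

test_that("the Poisson filter threshold matches a direct tail summation", {
    # lambda 1.0, a million windows, alpha 0.05
    expect_equal(poissonThreshold(1.0, 0.05 / 1e6),
                 tailThresholdOracle(1.0, 5e-8))
    for (lam in c(0.1, 0.5, 2, 7.3)) {
        for (lev in c(1e-3, 1e-6, 5e-8)) {
            expect_equal(poissonThreshold(lam, lev),
                         tailThresholdOracle(lam, lev))
        }
    }
    expect_equal(poissonThreshold(0, 0.01), 1L)
})

test_that("the filter retains signal windows and drops even-coverage noise", {
    set.seed(3)
    grid <- tileWindows(c(chr1 = 50000L), 50)
    n <- length(grid)
    counts <- cbind(s1 = rpois(n, 0.5), s2 = rpois(n, 0.5))
    counts[10:14, ] <- 30L     # one strong region
    x <- WindowCounts(counts, grid, c("A", "B"))
    fr <- poissonFilter(x, alpha = 0.05)
    expect_true(all(10:14 %in% retainedWindows(fr)))
    # retained = windows where some sample reaches its threshold
    thr <- filterThresholds(fr)
    manual <- which(counts[, 1] >= thr[1] | counts[, 2] >= thr[2])
    expect_equal(retainedWindows(fr), manual)
    # all-zero matrix: nothing retained, warning about dead samples
    x0 <- WindowCounts(matrix(0L, 10, 2), tileWindows(c(c1 = 500L), 50),
                       c("A", "B"))
    expect_warning(fr0 <- poissonFilter(x0), "all-zero")
    expect_length(retainedWindows(fr0), 0)
    # single window, alpha near 1: threshold 1, any nonzero window kept
    x1 <- WindowCounts(matrix(c(2L, 0L), 1, 2),
                       tileWindows(c(c1 = 50L), 50), c("A", "B"))
    fr1 <- suppressWarnings(poissonFilter(x1, alpha = 0.999))
    expect_equal(retainedWindows(fr1), 1L)
})

test_that("filter calibration on pure Poisson noise is Bonferroni-tight", {
    set.seed(99)
    grid <- tileWindows(c(chr1 = 50 * 50000L), 50)
    for (lam in c(0.3, 1, 3)) {
        counts <- cbind(s1 = rpois(50000, lam), s2 = rpois(50000, lam))
        x <- WindowCounts(counts, grid, c("A", "B"))
        fr <- poissonFilter(x, alpha = 0.05)
        # expected retention under the fitted rates
        p <- 1 - prod(ppois(filterThresholds(fr) - 1, filterRates(fr)))
        expected <- 50000 * p
        se <- sqrt(50000 * p * (1 - p))
        expect_lte(length(retainedWindows(fr)), expected + 3 * se + 1)
    }
})

test_that("count matrices round-trip through TSV", {
    set.seed(5)
    grid <- tileWindows(si, 50)
    counts <- matrix(rpois(2 * length(grid), 1), ncol = 2,
                     dimnames = list(NULL, c("a", "b")))
    x <- WindowCounts(counts, grid, c("A", "B"))
    tf <- tempfile(fileext = ".tsv")
    writeCountsTsv(x, tf)
    y <- readCountsTsv(tf, c("A", "B"), chromSizes = si)
    expect_equal(assay(y, "counts"), assay(x, "counts"))
    expect_equal(granges(rowRanges(y)), granges(rowRanges(x)))
})
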