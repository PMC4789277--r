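# Independent brute-force oracles used to validate the package's
# implementations.  They deliberately share no code path with the package:
# per-base loops, naive tail sums, textbook formulas.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
    library(SummarizedExperiment)
})

# per-base pileup: average depth per window, rounded half away from zero
pileupOracle <- function(grid, fragments) {
    sl <- GenomeInfoDb::seqlengths(grid)
    depth <- lapply(sl, function(L) integer(L))
    for (i in seq_along(fragments)) {
        chr <- as.character(seqnames(fragments))[i]
        for (b in start(fragments)[i]:end(fragments)[i])
            depth[[chr]][b] <- depth[[chr]][b] + 1L
    }
    vapply(seq_along(grid), function(w) {
        chr <- as.character(seqnames(grid))[w]
        v <- depth[[chr]][start(grid)[w]:end(grid)[w]]
        as.integer(floor(mean(v) + 0.5))
    }, integer(1))
}

# textbook BH step-up with monotonicity enforcement
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    for (i in rev(seq_len(n - 1))) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}

# gap-merged methylated runs via adjacent-index differences (independent of
# the rle-based implementation)
scanOracle <- function(status, maxGap, minWindows) {
    m <- which(status)
    if (!length(m))
        return(data.frame(from = integer(0), to = integer(0),
                          nMeth = integer(0)))
    grp <- cumsum(c(1L, as.integer(diff(m) - 1L > maxGap)))
    out <- do.call(rbind, lapply(split(m, grp), function(idx)
        data.frame(from = min(idx), to = max(idx), nMeth = length(idx))))
    rownames(out) <- NULL
    out[out$nMeth >= minWindows, , drop = FALSE]
}

# per-base feature classifier: label every base of the DMR, take the
# highest-priority label overlapped
featureOracle <- function(dmr, genes, upstream = 1000, downstream = 500,
                          flank = 1000) {
    pri <- c("promoter", "three_prime", "exon", "intron", "intergenic")
    if (length(genes) == 0L) return("intergenic")
    inAny <- function(b, starts, ends) any(b >= starts & b <= ends)
    promS <- promE <- tpS <- tpE <- exS <- exE <- txS <- txE <- integer(0)
    chrOf <- list(prom = character(0), tp = character(0),
                  ex = character(0), tx = character(0))
    for (i in seq_along(genes)) {
        chr <- as.character(seqnames(genes))[i]
        s <- start(genes)[i]; e <- end(genes)[i]
        plus <- as.character(strand(genes))[i] == "+"
        tss <- if (plus) s else e
        if (plus) { ps <- tss - upstream; pe <- tss + downstream - 1 }
        else { ps <- tss - downstream + 1; pe <- tss + upstream }
        promS <- c(promS, ps); promE <- c(promE, pe)
        chrOf$prom <- c(chrOf$prom, chr)
        ttsB <- if (plus) e else s - 1   # boundary coordinate
        tpS <- c(tpS, ttsB - flank + 1); tpE <- c(tpE, ttsB + flank)
        chrOf$tp <- c(chrOf$tp, chr)
        bl <- mcols(genes)$blocks[[i]]
        exS <- c(exS, s - 1 + start(bl)); exE <- c(exE, s - 1 + end(bl))
        chrOf$ex <- c(chrOf$ex, rep(chr, length(bl)))
        txS <- c(txS, s); txE <- c(txE, e)
        chrOf$tx <- c(chrOf$tx, chr)
    }
    best <- 5L
    chr <- as.character(seqnames(dmr))[1]
    for (b in start(dmr)[1]:end(dmr)[1]) {
        lab <- 5L
        if (inAny(b, promS[chrOf$prom == chr], promE[chrOf$prom == chr]))
            lab <- 1L
        else if (inAny(b, tpS[chrOf$tp == chr], tpE[chrOf$tp == chr]))
            lab <- 2L
        else if (inAny(b, exS[chrOf$ex == chr], exE[chrOf$ex == chr]))
            lab <- 3L
        else if (inAny(b, txS[chrOf$tx == chr], txE[chrOf$tx == chr]))
            lab <- 4L
        best <- min(best, lab)
    }
    pri[best]
}

# min edge-to-edge distance of a range to a set of islands
cgiDistanceOracle <- function(dmr, islands) {
    if (length(islands) == 0L) return(Inf)
    same <- as.character(seqnames(islands)) == as.character(seqnames(dmr))[1]
    if (!any(same)) return(Inf)
    s <- start(dmr)[1]; e <- end(dmr)[1]
    d <- vapply(which(same), function(i) {
        is <- start(islands)[i]; ie <- end(islands)[i]
        if (is <= e && ie >= s) 0 else max(is - e - 1, s - ie - 1)
    }, numeric(1))
    min(d)
}

# smallest c with Poisson upper tail P(X >= c) <= level, by direct summation
tailThresholdOracle <- function(lambda, level, cmax = 1000L) {
    for (cc in 1:cmax) {
        tail <- 1 - sum(dpois(0:(cc - 1), lambda))
        if (tail <= level) return(cc)
    }
    stop("no threshold found below ", cmax)
}

# closed-form three-Poisson posterior of the highest-rate component
posteriorOracle <- function(count, lambda, weights) {
    num <- weights * dpois(count, lambda)
    num[3] / sum(num)
}

# random valid three-Poisson fit for property tests
randomFit <- function() {
    lam <- sort(c(runif(1, 0.05, 1), runif(1, 2, 10), runif(1, 15, 60)))
    w <- runif(3, 0.05, 1); w <- w / sum(w)
    new("ThreePoissonFit", lambda = lam, weights = w,
        objective = numeric(0), converged = TRUE, nIter = 0L,
        degenerate = FALSE)
}

# small shared fixture for pipeline-level tests
smallBundle <- function(seed = 7, ...) {
    args <- list(outdir = tempfile("bundle"), nChroms = 2,
                 chromLength = 1e6, nGenes = 20, nIslands = 15,
                 truthCfg = truthConfig(nSharp01 = 20, nSharp10 = 20,
                                        nShared = 8, nInverseGenes = 6),
                 seed = seed)
    over <- list(...)
    args[names(over)] <- over
    do.call(simulateBundle, args)
}
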