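#' Construct a toy genome
#'
#' A deterministic stand-in for a reference assembly: \code{nChroms}
#' chromosomes named chr1..chrN, each of \code{chromLength} bp.
#'
#' @param nChroms number of chromosomes (>= 1).
#' @param chromLength chromosome length in bp.
#' @return a \code{Seqinfo}.
#' @examples
#' makeToyGenome(2, 5e6)
#' @export
makeToyGenome <- function(nChroms = 2L, chromLength = 5e6) {
    if (nChroms < 1L || chromLength < 1)
        stop("nChroms and chromLength must be positive")
    Seqinfo(paste0("chr", seq_len(nChroms)), rep(as.integer(chromLength),
                                                 nChroms))
}

# place n non-overlapping intervals of the given widths uniformly on the
# genome, optionally avoiding an exclusion set; bounded rejection sampling
.placeNonOverlapping <- function(si, widths, avoid = NULL,
                                 maxTries = 200L) {
    placed <- GRanges(seqinfo = si)
    sl <- seqlengths(si)
    for (w in widths) {
        ok <- FALSE
        for (tr in seq_len(maxTries)) {
            chr <- sample(names(sl), 1L, prob = sl / sum(sl))
            if (sl[chr] < w) next
            s <- sample.int(sl[chr] - w + 1L, 1L)
            cand <- GRanges(chr, IRanges(s, s + w - 1L), seqinfo = si)
            if (length(placed) && overlapsAny(cand, placed)) next
            if (!is.null(avoid) && length(avoid) &&
                overlapsAny(cand, avoid, ignore.strand = TRUE)) next
            placed <- c(placed, cand)
            ok <- TRUE
            break
        }
        if (!ok)
            stop("could not place interval of width ", w,
                 " without overlap after ", maxTries, " tries")
    }
    placed
}

# split a gene span into nExons exon blocks (BED12 convention: first block
# starts at the gene start, last block ends at the gene end)
.exonBlocks <- function(geneWidth, nExons) {
    if (nExons == 1L) return(IRanges(1L, geneWidth))
    # alternate exon/intron pieces: nExons exons, nExons-1 introns
    nPieces <- 2L * nExons - 1L
    len <- pmax(1L, as.integer(rmultinom(1L, geneWidth - nPieces,
                                         rep(1, nPieces))) + 1L)
    len[nPieces] <- geneWidth - sum(len[-nPieces])
    ends <- cumsum(len)
    starts <- ends - len + 1L
    keep <- seq(1L, nPieces, by = 2L)
    IRanges(starts[keep], ends[keep])
}

#' Generate toy gene models and CpG islands
#'
#' Genes are placed uniformly without overlap, with random strand and 1-8
#' exons spanning the full gene body (BED12 convention).  Islands are
#' placed without overlapping each other; a configurable fraction is
#' forced inside gene promoter windows, the rest placed anywhere.
#'
#' @param genome a \code{Seqinfo} from [makeToyGenome()].
#' @param nGenes number of genes.
#' @param nIslands number of CpG islands.
#' @param fracIslandsInPromoters fraction of islands forced to overlap a
#'   promoter window (default 0.3).
#' @param seed RNG seed (RNG state is restored on exit).
#' @param geneWidthRange gene length range in bp (default 5-50 kb).
#' @param islandWidthRange island length range in bp (default 0.2-2 kb).
#' @return list with elements \code{genes} (\code{GRanges} with
#'   \code{name}, \code{score} and \code{blocks} columns, BED12-ready) and
#'   \code{islands} (\code{GRanges}).
#' @export
makeAnnotations <- function(genome, nGenes, nIslands,
                            fracIslandsInPromoters = 0.3, seed = 1L,
                            geneWidthRange = c(5e3, 5e4),
                            islandWidthRange = c(200, 2000)) {
    withr::local_seed(seed)
    genes <- GRanges(seqinfo = genome)
    if (nGenes > 0L) {
        w <- as.integer(round(runif(nGenes, geneWidthRange[1],
                                    geneWidthRange[2])))
        genes <- .placeNonOverlapping(genome, w)
        strand(genes) <- sample(c("+", "-"), nGenes, replace = TRUE)
        nEx <- sample.int(8L, nGenes, replace = TRUE)
        blocks <- IRanges::IRangesList(lapply(seq_len(nGenes), function(i)
            .exonBlocks(width(genes)[i], nEx[i])))
        mcols(genes)$name <- sprintf("gene%04d", seq_len(nGenes))
        mcols(genes)$score <- 0L
        mcols(genes)$blocks <- blocks
    } else {
        mcols(genes)$name <- character(0)
        mcols(genes)$score <- integer(0)
        mcols(genes)$blocks <- IRanges::IRangesList()
    }
    islands <- GRanges(seqinfo = genome)
    if (nIslands > 0L) {
        wI <- as.integer(round(runif(nIslands, islandWidthRange[1],
                                     islandWidthRange[2])))
        nInProm <- round(fracIslandsInPromoters * nIslands)
        if (nInProm > 0L && nGenes == 0L)
            stop("cannot place islands in promoters without genes")
        if (nInProm > 0L) {
            prom <- promoterInterval(genes)
            pick <- sample.int(length(prom), nInProm,
                               replace = nInProm > length(prom))
            for (j in seq_len(nInProm)) {
                p <- prom[pick[j]]
                w <- min(wI[j], width(p))
                s <- start(p) + sample.int(width(p) - w + 1L, 1L) - 1L
                cand <- GRanges(seqnames(p), IRanges(s, s + w - 1L),
                                seqinfo = genome)
                if (length(islands) && overlapsAny(cand, islands,
                                                   ignore.strand = TRUE))
                    next
                islands <- c(islands, cand)
            }
        }
        nLeft <- nIslands - length(islands)
        if (nLeft > 0L)
            islands <- c(islands,
                         .placeNonOverlapping(genome,
                                              wI[seq_len(nLeft) + nInProm],
                                              avoid = islands))
        islands <- sort(islands, ignore.strand = TRUE)
    }
    list(genes = sort(genes, ignore.strand = TRUE), islands = islands)
}

#' Default truth-planting configuration
#'
#' Region counts, per-window Poisson rates and geometry used by
#' [plantTruth()].  The default rates (background 0.3, methylated 25,
#' quantitative pair 25/60 counts per window) separate the mixture
#' components cleanly at the simulated sequencing depth; all are
#' configurable.
#'
#' @param nSharp01,nSharp10 numbers of sharp regions hyper-/hypomethylated
#'   in group B.
#' @param nQuantitative number of quantitative regions (methylated in both
#'   groups at different rates).
#' @param nShared number of shared-methylated decoy regions (identical in
#'   both groups).
#' @param nInverseGenes number of genes given a promoter sharp region and
#'   an opposite-direction planted expression change.
#' @param regionWindows integer range of region widths in windows.
#' @param backgroundRate,methylatedRate per-window Poisson rates.
#' @param quantRates length-2 rates (group A, group B) for quantitative
#'   regions.
#' @param window window width in bp.
#' @return a named list.
#' @export
truthConfig <- function(nSharp01 = 100L, nSharp10 = 100L,
                        nQuantitative = 0L, nShared = 25L,
                        nInverseGenes = 10L,
                        regionWindows = c(4L, 10L),
                        backgroundRate = 0.3, methylatedRate = 25,
                        quantRates = c(25, 60), window = 50L) {
    list(nSharp01 = nSharp01, nSharp10 = nSharp10,
         nQuantitative = nQuantitative, nShared = nShared,
         nInverseGenes = nInverseGenes, regionWindows = regionWindows,
         backgroundRate = backgroundRate, methylatedRate = methylatedRate,
         quantRates = quantRates, window = window)
}

#' Plant ground-truth methylation structure and DE genes
#'
#' Plants window-aligned, non-overlapping truth regions of four kinds:
#' sharp01 (methylated in group B only), sharp10 (group A only),
#' quantitative (methylated in both groups at different rates) and
#' shared_methylated decoys (identical in both groups).  The first
#' \code{nInverseGenes} sharp regions are forced to overlap the promoters
#' of randomly chosen genes, and those genes receive a planted expression
#' change opposite in direction to their promoter methylation change; extra
#' concordant DE genes are planted as negative controls for the
#' inverse-correlation join.
#'
#' @param genome a \code{Seqinfo}.
#' @param genes gene models from [makeAnnotations()].
#' @param config list from [truthConfig()].
#' @param nSamples number of samples (for size factors).
#' @param seed RNG seed (RNG state is restored on exit).
#' @return a \linkS4class{MethylationTruth}.
#' @export
plantTruth <- function(genome, genes, config = truthConfig(),
                       nSamples = 6L, seed = 1L) {
    withr::local_seed(seed)
    w <- config$window
    nInv <- config$nInverseGenes
    nSharp <- config$nSharp01 + config$nSharp10
    if (nInv > nSharp)
        stop("more inverse genes requested than sharp regions")
    if (nInv > length(genes))
        stop("more inverse genes requested than genes available")
    # shuffle the sharp kinds so promoter-anchored regions carry a random
    # mix of both directions
    sharpKinds <- sample(c(rep("sharp01", config$nSharp01),
                           rep("sharp10", config$nSharp10)))
    kinds <- c(sharpKinds,
               rep("quantitative", config$nQuantitative),
               rep("shared_methylated", config$nShared))
    nReg <- length(kinds)
    widths <- sample(seq(config$regionWindows[1], config$regionWindows[2]),
                     nReg, replace = TRUE) * w

    regions <- GRanges(seqinfo = genome)
    geneOf <- character(0)
    sl <- seqlengths(genome)
    # promoter-anchored sharp regions first (the inverse genes)
    invGenes <- character(0)
    if (nInv > 0L) {
        pick <- sample.int(length(genes), nInv)
        invGenes <- mcols(genes)$name[pick]
        prom <- promoterInterval(genes[pick])
        for (j in seq_len(nInv)) {
            # window-aligned region starting at the window containing the
            # promoter midpoint, so it always overlaps the promoter
            chr <- as.character(seqnames(prom))[j]
            mid <- (start(prom)[j] + end(prom)[j]) %/% 2L
            s <- ((mid - 1L) %/% w) * w + 1L
            e <- min(s + widths[j] - 1L, sl[chr])
            cand <- GRanges(chr, IRanges(s, e), seqinfo = genome)
            if (length(regions) && overlapsAny(cand, regions,
                                               ignore.strand = TRUE))
                stop("promoter-anchored truth regions collide; ",
                     "use fewer inverse genes or a larger genome")
            regions <- c(regions, cand)
            geneOf <- c(geneOf, invGenes[j])
        }
    }
    # remaining regions anywhere, window-aligned, non-overlapping, and
    # clear of every promoter so that no extra inverse pairing can arise
    promAll <- if (length(genes)) promoterInterval(genes)
               else GRanges(seqinfo = genome)
    for (j in seq_len(nReg - nInv) + nInv) {
        ok <- FALSE
        for (tr in seq_len(500L)) {
            chr <- sample(names(sl), 1L, prob = sl / sum(sl))
            nWin <- (sl[chr] - widths[j] + 1L) %/% w
            if (nWin < 1L) next
            s <- (sample.int(nWin, 1L) - 1L) * w + 1L
            cand <- GRanges(chr, IRanges(s, s + widths[j] - 1L),
                            seqinfo = genome)
            if (length(regions) && overlapsAny(cand, regions,
                                               ignore.strand = TRUE)) next
            if (length(promAll) && overlapsAny(cand, promAll,
                                               ignore.strand = TRUE)) next
            regions <- c(regions, cand)
            geneOf <- c(geneOf, NA_character_)
            ok <- TRUE
            break
        }
        if (!ok) stop("could not place truth region without overlap")
    }
    bg <- config$backgroundRate
    me <- config$methylatedRate
    rateA <- ifelse(kinds == "sharp01", bg,
             ifelse(kinds == "sharp10", me,
             ifelse(kinds == "quantitative", config$quantRates[1], me)))
    rateB <- ifelse(kinds == "sharp01", me,
             ifelse(kinds == "sharp10", bg,
             ifelse(kinds == "quantitative", config$quantRates[2], me)))
    mcols(regions)$kind <- kinds
    mcols(regions)$rateA <- rateA
    mcols(regions)$rateB <- rateB
    mcols(regions)$gene <- geneOf

    sizeFactors <- exp(runif(nSamples, log(0.7), log(1.4)))
    names(sizeFactors) <- paste0("sample", seq_len(nSamples))

    # planted DE: inverse genes get fold changes opposite to their promoter
    # methylation direction; a few concordant / non-promoter DE genes are
    # planted as negative controls
    de <- data.frame(gene = character(0), foldChange = numeric(0),
                     padj = numeric(0), stringsAsFactors = FALSE)
    if (nInv > 0L) {
        invKind <- kinds[seq_len(nInv)]
        fold <- ifelse(invKind == "sharp01",
                       runif(nInv, 0.1, 0.7),      # hyper promoter, down
                       runif(nInv, 1.5, 8))        # hypo promoter, up
        de <- rbind(de, data.frame(gene = invGenes, foldChange = fold,
                                   padj = runif(nInv, 0, 0.04),
                                   stringsAsFactors = FALSE))
    }
    rest <- setdiff(mcols(genes)$name, invGenes)
    nExtra <- min(length(rest), max(2L, nInv %/% 2L))
    if (nExtra > 0L && length(genes) > 0L) {
        extra <- sample(rest, nExtra)
        de <- rbind(de, data.frame(
            gene = extra,
            foldChange = exp(runif(nExtra, log(0.2), log(5))),
            padj = runif(nExtra, 0, 0.04), stringsAsFactors = FALSE))
    }
    new("MethylationTruth", regions = regions, sizeFactors = sizeFactors,
        deTable = de, inverseGenes = invGenes, backgroundRate = bg)
}

#' A two-group sample design
#'
#' @param nA,nB samples in groups A and B.
#' @param groups group labels (default \code{c("A", "B")}; the second is
#'   the fibrotic/test group, the numerator of fold changes).
#' @return data.frame with columns \code{sample} and \code{group}.
#' @export
sampleDesign <- function(nA = 3L, nB = 3L, groups = c("A", "B")) {
    data.frame(sample = paste0("sample", seq_len(nA + nB)),
               group = factor(rep(groups, c(nA, nB)), levels = groups),
               stringsAsFactors = FALSE)
}

#' Simulate window counts from planted truth
#'
#' Counts are drawn independently per window and sample from
#' Poisson(sizeFactor_s x rate), where the rate is the planted region rate
#' of the sample's group for windows inside a truth region and the
#' background rate elsewhere.  Windows overlapping a region boundary take
#' the region rate (regions are planted window-aligned, so this is exact
#' for generated truth).
#'
#' @param genome a \code{Seqinfo}.
#' @param truth a \linkS4class{MethylationTruth}.
#' @param design data.frame from [sampleDesign()].
#' @param window window width in bp (default 50).
#' @param seed RNG seed (RNG state is restored on exit).
#' @return a \linkS4class{WindowCounts}.
#' @export
simulateCounts <- function(genome, truth, design, window = 50L, seed = 1L) {
    if (min(table(design$group)) < 2L)
        stop("need at least 2 samples per group")
    withr::local_seed(seed)
    grid <- tileWindows(genome, window)
    n <- length(grid)
    sf <- truth@sizeFactors
    if (length(sf) != nrow(design))
        stop("truth size factors do not match the design")
    rateA <- rep(truth@backgroundRate, n)
    rateB <- rateA
    hits <- findOverlaps(grid, truth@regions, ignore.strand = TRUE)
    rateA[queryHits(hits)] <- mcols(truth@regions)$rateA[subjectHits(hits)]
    rateB[queryHits(hits)] <- mcols(truth@regions)$rateB[subjectHits(hits)]
    counts <- matrix(0L, n, nrow(design))
    colnames(counts) <- design$sample
    isB <- design$group == levels(factor(design$group))[2L]
    for (s in seq_len(nrow(design))) {
        r <- if (isB[s]) rateB else rateA
        counts[, s] <- rpois(n, sf[s] * r)
    }
    WindowCounts(counts, grid, design$group, sizeFactor = unname(sf))
}

#' Simulate a differential-expression table
#'
#' Planted DE genes carry their planted fold change and adjusted-p
#' surrogate (< 0.05); all other genes get fold changes near 1 and adjusted
#' p at or above 0.05.  The pipeline consumes, never computes, expression
#' p-values, so the surrogates are planted directly.
#'
#' @param genes gene models (\code{GRanges} with \code{name}).
#' @param truth a \linkS4class{MethylationTruth}.
#' @param seed RNG seed (RNG state is restored on exit).
#' @return data.frame with columns \code{gene}, \code{fold_change},
#'   \code{padj}, one row per gene.
#' @export
simulateExpression <- function(genes, truth, seed = 1L) {
    withr::local_seed(seed)
    ids <- mcols(genes)$name
    de <- truth@deTable
    if (nrow(de) && !all(de$gene %in% ids))
        stop("planted DE gene(s) not in the gene set: ",
             paste(setdiff(de$gene, ids), collapse = ", "))
    fc <- exp(rnorm(length(ids), 0, 0.05))
    padj <- runif(length(ids), 0.05, 1)
    m <- match(de$gene, ids)
    fc[m] <- de$foldChange
    padj[m] <- de$padj
    data.frame(gene = ids, fold_change = fc, padj = padj,
               stringsAsFactors = FALSE)
}

#' Write truth regions as BED6
#'
#' Name is the region kind; score is the rate ratio (B over A) capped at
#' 1000 for BED display.
#'
#' @param truth a \linkS4class{MethylationTruth}.
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeTruthBed <- function(truth, path) {
    r <- truth@regions
    ratio <- mcols(r)$rateB / pmax(mcols(r)$rateA, 1e-9)
    df <- data.frame(chrom = as.character(seqnames(r)),
                     start = start(r) - 1L, end = end(r),
                     name = mcols(r)$kind,
                     score = round(pmin(ratio, 1000), 3),
                     strand = ".")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
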