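#' Promoter windows of gene models
#'
#' The promoter is the strand-aware window from \code{upstream} bp before to
#' \code{downstream} bp after the transcription start site, clipped to the
#' chromosome.  Defaults follow the common asymmetric convention of 1000 bp
#' upstream / 500 bp downstream.
#'
#' @param genes \code{GRanges} of gene models (strand required).
#' @param upstream,downstream extent in bp (defaults 1000 and 500).
#' @return \code{GRanges} of promoter windows, one per gene.
#' @export
promoterInterval <- function(genes, upstream = 1000L, downstream = 500L) {
    trim(suppressWarnings(
        promoters(genes, upstream = upstream, downstream = downstream)))
}

#' 3'-end windows of gene models
#'
#' A symmetric window of \code{flank} bp on each side of the strand-aware
#' transcription termination site, clipped to the chromosome.
#'
#' @param genes \code{GRanges} of gene models (strand required).
#' @param flank extent in bp on each side of the TTS (default 1000).
#' @return \code{GRanges} of 3'-end windows, one per gene.
#' @export
threePrimeInterval <- function(genes, flank = 1000L) {
    plus <- as.character(strand(genes)) == "+"
    # TTS boundary coordinate (0-based half-open): end for +, start for -
    tts <- ifelse(plus, end(genes), start(genes) - 1L)
    out <- suppressWarnings(
        GRanges(seqnames(genes), IRanges(pmax(tts - flank + 1L, 1L),
                                         tts + flank),
                strand = strand(genes), seqinfo = seqinfo(genes)))
    names(out) <- names(genes)
    mcols(out) <- mcols(genes)
    trim(out)
}

#' Absolute exon ranges of gene models
#'
#' Gene models carry their exon structure as block ranges relative to the
#' gene start (BED12 convention, as imported by rtracklayer); this resolves
#' them to absolute coordinates.
#'
#' @param genes \code{GRanges} with an IRangesList \code{blocks} column.
#' @return \code{GRangesList} of absolute exon ranges, one element per gene.
#' @export
exonRanges <- function(genes) {
    if (is.null(mcols(genes)$blocks))
        stop("gene models must carry a 'blocks' column (BED12 exons)")
    bl <- mcols(genes)$blocks
    shifted <- IRanges::shift(bl, start(genes) - 1L)
    GRangesList(lapply(seq_along(genes), function(i)
        GRanges(seqnames(genes)[i], shifted[[i]],
                strand = strand(genes)[i],
                seqinfo = seqinfo(genes))))
}

.featurePriority <- c("promoter", "three_prime", "exon", "intron",
                      "intergenic")

#' Gene-model context of DMRs with fixed overlap priority
#'
#' Each DMR is assigned the single highest-priority category among
#' everything it overlaps, pooled across all genes:
#' promoter > 3' end > exon > intron > intergenic.  Introns are the
#' transcript span minus the exons; a DMR overlapping no gene feature is
#' intergenic.
#'
#' @param dmrs \code{GRanges} of DMRs.
#' @param genes \code{GRanges} gene models with \code{name} and
#'   \code{blocks} columns.
#' @param upstream,downstream promoter extent, see [promoterInterval()].
#' @param threePrimeFlank 3'-end extent, see [threePrimeInterval()].
#' @return data.frame with one row per DMR: \code{category} (factor with
#'   the priority levels) and \code{genes} (comma-separated ids of all
#'   overlapped genes, across all feature categories).
#' @export
classifyFeature <- function(dmrs, genes, upstream = 1000L,
                            downstream = 500L, threePrimeFlank = 1000L) {
    n <- length(dmrs)
    cat <- factor(rep("intergenic", n), levels = .featurePriority)
    hitGenes <- rep("", n)
    if (length(genes) > 0L && n > 0L) {
        geneIds <- mcols(genes)$name
        if (is.null(geneIds)) geneIds <- paste0("gene", seq_along(genes))
        prom <- promoterInterval(genes, upstream, downstream)
        tp <- threePrimeInterval(genes, threePrimeFlank)
        ex <- unlist(exonRanges(genes))
        exGene <- rep(geneIds, lengths(exonRanges(genes)))
        feats <- list(
            promoter = list(gr = prom, gene = geneIds),
            three_prime = list(gr = tp, gene = geneIds),
            exon = list(gr = ex, gene = exGene),
            intron = list(gr = granges(genes), gene = geneIds))
        # introns via the transcript span: exon overlap outranks it anyway,
        # so transcript-minus-exon equals "transcript overlap not claimed
        # by a higher category" only when the DMR misses every exon; to be
        # exact we subtract exons explicitly
        introns <- GenomicRanges::setdiff(
            reduce(granges(genes), ignore.strand = TRUE),
            reduce(granges(ex), ignore.strand = TRUE),
            ignore.strand = TRUE)
        feats$intron$gr <- introns
        feats$intron$gene <- NULL
        assigned <- rep(FALSE, n)
        allGenes <- vector("list", n)
        for (f in c("promoter", "three_prime", "exon", "intron")) {
            hits <- findOverlaps(dmrs, feats[[f]]$gr, ignore.strand = TRUE)
            hit <- unique(queryHits(hits))
            newly <- hit[!assigned[hit]]
            cat[newly] <- f
            assigned[hit] <- TRUE
            if (!is.null(feats[[f]]$gene)) {
                g <- split(feats[[f]]$gene[subjectHits(hits)],
                           queryHits(hits))
                for (q in names(g))
                    allGenes[[as.integer(q)]] <-
                        c(allGenes[[as.integer(q)]], g[[q]])
            }
        }
        # genes overlapped via the raw transcript span (for reporting)
        hits <- findOverlaps(dmrs, genes, ignore.strand = TRUE)
        g <- split(geneIds[subjectHits(hits)], queryHits(hits))
        for (q in names(g))
            allGenes[[as.integer(q)]] <- c(allGenes[[as.integer(q)]], g[[q]])
        hitGenes <- vapply(allGenes, function(v)
            paste(sort(unique(v)), collapse = ","), character(1))
    }
    data.frame(category = cat, genes = hitGenes, stringsAsFactors = FALSE)
}

.cgiLevels <- c("island", "shore", "shelf", "open_sea")

#' CpG-island context of DMRs
#'
#' Islands are merged, then each DMR is labelled by its edge-to-edge
#' distance d to the nearest island: island (overlap, d = 0), shore
#' (0 < d <= 2000), shelf (2000 < d <= 4000), open sea (d > 4000).
#'
#' @param dmrs \code{GRanges} of DMRs.
#' @param islands \code{GRanges} of CpG islands.
#' @param shore,shelf band widths in bp (defaults 2000 and 2000: shores end
#'   at 2 kb, shelves at 4 kb from an island).
#' @return data.frame with one row per DMR: \code{context} (factor) and
#'   \code{distance} (bp to the nearest island; Inf when no islands exist).
#' @export
classifyCgiContext <- function(dmrs, islands, shore = 2000L, shelf = 2000L) {
    n <- length(dmrs)
    if (length(islands) == 0L)
        return(data.frame(
            context = factor(rep("open_sea", n), levels = .cgiLevels),
            distance = rep(Inf, n)))
    islands <- reduce(islands, ignore.strand = TRUE)
    d <- rep(Inf, n)
    hit <- distanceToNearest(dmrs, islands, ignore.strand = TRUE)
    d[queryHits(hit)] <- mcols(hit)$distance
    ov <- overlapsAny(dmrs, islands, ignore.strand = TRUE)
    d[ov] <- 0
    ctx <- ifelse(ov, "island",
           ifelse(d <= shore, "shore",
           ifelse(d <= shore + shelf, "shelf", "open_sea")))
    data.frame(context = factor(ctx, levels = .cgiLevels), distance = d)
}

#' Category proportions per DMR direction
#'
#' Summarises annotated DMRs as the percentage of hyper- (01) and
#' hypomethylated (10) DMRs falling in each category.
#'
#' @param calls factor or character of category calls, one per DMR.
#' @param direction character of direction codes ("01"/"10"), same length.
#' @return data.frame: \code{direction}, \code{category}, \code{count},
#'   \code{percent}; percentages sum to 100 within each direction.  Empty
#'   input gives an empty frame.
#' @export
contextProportions <- function(calls, direction) {
    stopifnot(length(calls) == length(direction))
    if (length(calls) == 0L)
        return(data.frame(direction = character(0), category = character(0),
                          count = integer(0), percent = numeric(0)))
    calls <- factor(calls)
    out <- do.call(rbind, lapply(unique(direction), function(d) {
        tab <- table(calls[direction == d])
        data.frame(direction = d, category = names(tab),
                   count = as.integer(tab),
                   percent = 100 * as.integer(tab) / sum(tab),
                   row.names = NULL)
    }))
    out
}

#' Annotate tested DMRs with feature and CGI context
#'
#' @param dmrs \code{GRanges} of DMRs.
#' @param genes gene models (\code{GRanges}, BED12-style blocks).
#' @param islands CpG islands (\code{GRanges}).
#' @param ... passed to [classifyFeature()].
#' @return the DMRs with added metadata columns \code{category},
#'   \code{overlapGenes}, \code{cgiContext}, \code{cgiDistance}.
#' @export
annotateDmrs <- function(dmrs, genes, islands, ...) {
    fc <- classifyFeature(dmrs, genes, ...)
    cc <- classifyCgiContext(dmrs, islands)
    mcols(dmrs)$category <- as.character(fc$category)
    mcols(dmrs)$overlapGenes <- fc$genes
    mcols(dmrs)$cgiContext <- as.character(cc$context)
    mcols(dmrs)$cgiDistance <- cc$distance
    dmrs
}
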