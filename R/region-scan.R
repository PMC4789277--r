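#' Gap-tolerant runs of methylated windows in one status vector
#'
#' Core of the segmentation scan: maximal runs of methylated windows, where
#' runs separated by at most \code{maxGap} unmethylated windows are merged,
#' and merged runs with fewer than \code{minWindows} methylated members are
#' discarded.  Operates on a single chromosome's genome-ordered status
#' vector; window indices are positions in that vector.
#'
#' @param status logical vector, genome-ordered methylation status of one
#'   sample on one chromosome.
#' @param maxGap maximal number of consecutive unmethylated windows bridged
#'   inside a segment (default 2).
#' @param minWindows minimal number of methylated windows in a kept segment
#'   (default 2).
#' @return data.frame with one row per segment: \code{from}, \code{to}
#'   (first/last window index), \code{nMeth}, \code{nGap}.
#' @examples
#' statusRuns(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), maxGap = 1)
#' @export
statusRuns <- function(status, maxGap = 2L, minWindows = 2L) {
    stopifnot(is.logical(status), maxGap >= 0L, minWindows >= 1L)
    empty <- data.frame(from = integer(0), to = integer(0),
                        nMeth = integer(0), nGap = integer(0))
    if (!any(status)) return(empty)
    r <- rle(status)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    meth <- which(r$values)
    # merge consecutive methylated runs while the gap run between them is
    # short enough; gap runs strictly between two methylated runs only
    segFrom <- starts[meth[1L]]
    segTo <- ends[meth[1L]]
    segMeth <- r$lengths[meth[1L]]
    segGap <- 0L
    out <- empty
    flush <- function(out, from, to, nMeth, nGap) {
        if (nMeth >= minWindows)
            out <- rbind(out, data.frame(from = from, to = to,
                                         nMeth = nMeth, nGap = nGap))
        out
    }
    for (i in seq_along(meth)[-1L]) {
        gap <- starts[meth[i]] - segTo - 1L
        if (gap <= maxGap) {
            segTo <- ends[meth[i]]
            segMeth <- segMeth + r$lengths[meth[i]]
            segGap <- segGap + gap
        } else {
            out <- flush(out, segFrom, segTo, segMeth, segGap)
            segFrom <- starts[meth[i]]
            segTo <- ends[meth[i]]
            segMeth <- r$lengths[meth[i]]
            segGap <- 0L
        }
    }
    flush(out, segFrom, segTo, segMeth, segGap)
}

#' Per-sample methylation segments across the genome
#'
#' Applies [statusRuns()] per chromosome and sample and returns the
#' segments as genomic intervals.  Never merges across chromosomes.
#'
#' @param status logical matrix, windows x samples, aligned to \code{grid}.
#' @param grid \code{GRanges} window grid.
#' @param maxGap,minWindows see [statusRuns()].
#' @return \code{GRanges} with metadata columns \code{sample},
#'   \code{fromWindow}, \code{toWindow} (global window indices),
#'   \code{nMeth}, \code{nGap}.
#' @export
scanSegments <- function(status, grid, maxGap = 2L, minWindows = 2L) {
    stopifnot(nrow(status) == length(grid))
    chr <- as.character(seqnames(grid))
    offs <- split(seq_along(grid), chr)
    segs <- list()
    for (s in seq_len(ncol(status))) {
        sid <- colnames(status)[s]
        if (is.null(sid)) sid <- paste0("sample", s)
        for (cn in names(offs)) {
            idx <- offs[[cn]]
            runs <- statusRuns(status[idx, s], maxGap, minWindows)
            if (nrow(runs) == 0L) next
            from <- idx[runs$from]
            to <- idx[runs$to]
            segs[[length(segs) + 1L]] <- GRanges(
                cn, IRanges(start(grid)[from], end(grid)[to]),
                seqinfo = seqinfo(grid),
                sample = sid, fromWindow = from, toWindow = to,
                nMeth = runs$nMeth, nGap = runs$nGap)
        }
    }
    if (length(segs) == 0L)
        return(GRanges(seqinfo = seqinfo(grid),
                       sample = character(0), fromWindow = integer(0),
                       toWindow = integer(0), nMeth = integer(0),
                       nGap = integer(0)))
    sort(do.call(c, segs), ignore.strand = TRUE)
}

#' Cross-sample candidate regions from per-sample segments
#'
#' Overlapping segments from any samples are unioned into maximal candidate
#' intervals (the units of differential testing).  Each sample's status over
#' a candidate is methylated when at least \code{majority} of the
#' candidate's windows are methylated in that sample.
#'
#' @param segments \code{GRanges} from [scanSegments()].
#' @param status logical matrix, windows x samples, aligned to \code{grid}.
#' @param grid \code{GRanges} window grid.
#' @param majority fraction of candidate windows that must be methylated for
#'   a sample to be called methylated over the candidate (default 0.5).
#' @return \code{GRanges} of candidates with metadata columns
#'   \code{candidate} (id), \code{nWindows}, and a logical matrix column
#'   \code{status} (candidates x samples).
#' @export
candidateRegions <- function(segments, status, grid, majority = 0.5) {
    cand <- reduce(segments, ignore.strand = TRUE)
    if (length(cand) == 0L) {
        mcols(cand)$candidate <- character(0)
        mcols(cand)$nWindows <- integer(0)
        mcols(cand)$status <- matrix(FALSE, 0L, ncol(status))
        return(cand)
    }
    hits <- findOverlaps(grid, cand, ignore.strand = TRUE)
    winByCand <- split(queryHits(hits), subjectHits(hits))
    nS <- ncol(status)
    st <- matrix(FALSE, length(cand), nS)
    colnames(st) <- colnames(status)
    nW <- integer(length(cand))
    for (i in seq_along(cand)) {
        w <- winByCand[[as.character(i)]]
        nW[i] <- length(w)
        st[i, ] <- colMeans(status[w, , drop = FALSE]) >= majority
    }
    mcols(cand)$candidate <- sprintf("cand%05d", seq_along(cand))
    mcols(cand)$nWindows <- nW
    mcols(cand)$status <- st
    mcols(cand)$windows <- IRanges::IntegerList(
        lapply(seq_along(cand), function(i) winByCand[[as.character(i)]]))
    cand
}
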