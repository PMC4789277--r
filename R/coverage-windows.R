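#' Extend aligned fragments to a fixed length
#'
#' Enrichment sequencing reads tag only the 5' end of the captured fragment;
#' coverage should reflect the whole fragment.  Each stranded interval is
#' anchored at its 5' end and resized to \code{targetLength}, then clipped to
#' the chromosome bounds taken from \code{seqinfo(fragments)}.
#'
#' @param fragments \code{GRanges} of aligned fragments with strand and a
#'   \code{Seqinfo} carrying chromosome lengths.
#' @param targetLength integer, the average fragment length in bp.
#' @return \code{GRanges} of extended, clipped fragments.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000)
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150),
#'                              strand = "+", seqinfo = si)
#' extendFragments(fr, 120)  # 101..220
#' @export
extendFragments <- function(fragments, targetLength) {
    stopifnot(is(fragments, "GRanges"))
    if (targetLength < 1) stop("targetLength must be >= 1")
    unstranded <- as.character(strand(fragments)) == "*"
    if (any(unstranded & width(fragments) != targetLength))
        stop("unstranded fragments of length != targetLength: ",
             "extension direction is ambiguous")
    # out-of-bound ranges are expected transiently; trimming is the contract
    out <- suppressWarnings(resize(fragments, width = targetLength,
                                   fix = "start", ignore.strand = FALSE))
    trim(out)
}

#' Tile a genome in fixed-width windows
#'
#' Every chromosome is covered by consecutive non-overlapping windows of
#' width \code{w}; the last window of a chromosome is truncated when the
#' length is not a multiple of \code{w}.  Windows are ordered by chromosome,
#' then position.
#'
#' @param chromSizes a \code{Seqinfo}, or a named integer vector of
#'   chromosome lengths.
#' @param w window width in bp (default 50).
#' @return \code{GRanges} of windows carrying the genome's \code{Seqinfo}.
#' @examples
#' tileWindows(c(chrA = 160), w = 50)  # 4 windows, last of width 10
#' @export
tileWindows <- function(chromSizes, w = 50L) {
    if (w < 1) stop("window width must be >= 1")
    si <- if (is(chromSizes, "Seqinfo")) chromSizes
          else Seqinfo(names(chromSizes), as.integer(chromSizes))
    sl <- seqlengths(si)
    # built directly rather than via tileGenome so chromosomes shorter than
    # one window still yield their single truncated window
    grl <- lapply(names(sl), function(cn) {
        st <- seq.int(1L, sl[cn], by = w)
        GRanges(cn, IRanges(st, pmin(st + w - 1L, sl[cn])), seqinfo = si)
    })
    do.call(c, grl)
}

# round half away from zero; base round() rounds half to even
.roundHalfUp <- function(x) floor(x + 0.5)

#' Window-level coverage counts from extended fragments
#'
#' For each sample, computes the per-base fragment depth, averages it over
#' each window, and rounds half away from zero to an integer count.
#' Truncated terminal windows are averaged over their actual width.
#'
#' @param grid \code{GRanges} window grid from [tileWindows()].
#' @param fragmentsList named list of \code{GRanges}, one element of
#'   extended fragments per sample.
#' @param group group labels, one per sample (defaults to a single group).
#' @return a \linkS4class{WindowCounts} object.
#' @export
countCoverage <- function(grid, fragmentsList,
                          group = rep("all", length(fragmentsList))) {
    stopifnot(is(grid, "GRanges"), is.list(fragmentsList))
    sl <- seqlengths(seqinfo(grid))
    counts <- vapply(fragmentsList, function(fr) {
        bad <- !as.character(seqnames(fr)) %in% names(sl)
        if (any(bad))
            stop("fragments on unknown chromosome: ",
                 paste(unique(as.character(seqnames(fr))[bad]), collapse = ", "))
        cov <- coverage(fr, width = sl)
        v <- GenomicRanges::binnedAverage(grid, cov, "m")$m
        as.integer(.roundHalfUp(v))
    }, integer(length(grid)))
    if (is.null(names(fragmentsList)))
        colnames(counts) <- paste0("sample", seq_along(fragmentsList))
    WindowCounts(counts, grid, group)
}

#' Minimal count significant under an even-coverage Poisson null
#'
#' The smallest integer c with upper-tail probability
#' P(Poisson(lambda) >= c) at or below \code{level}.
#'
#' @param lambda Poisson rate.
#' @param level per-window significance level (already multiplicity
#'   corrected by the caller).
#' @return integer threshold, at least 1.
#' @export
poissonThreshold <- function(lambda, level) {
    if (lambda <= 0) return(1L)
    # P(X >= c) <= level  <=>  P(X <= c-1) >= 1-level  <=>  c-1 >= qpois(...)
    c0 <- qpois(level, lambda, lower.tail = FALSE) + 1L
    max(1L, as.integer(c0))
}

#' Poisson false-discovery window filter
#'
#' Removes windows where no sample has a count exceeding what even coverage
#' of its reads across the genome would explain.  Each sample's rate is
#' estimated as its mean count per window; the per-sample count threshold is
#' the minimal count whose Poisson upper-tail probability falls below the
#' Bonferroni-corrected level \code{alpha / nWindows}.  A window is retained
#' when at least one sample reaches its threshold.
#'
#' @param x a \linkS4class{WindowCounts} object.
#' @param alpha family-wise level across windows (default 0.05).
#' @return a \linkS4class{PoissonFilterResult}.
#' @export
poissonFilter <- function(x, alpha = 0.05) {
    stopifnot(is(x, "WindowCounts"))
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    counts <- assay(x, "counts")
    n <- nrow(counts)
    if (n == 0L) stop("empty count matrix")
    lambda <- colMeans(counts)
    if (any(lambda == 0))
        warning("sample(s) with all-zero counts contribute nothing to the filter: ",
                paste(colnames(counts)[lambda == 0], collapse = ", "))
    level <- alpha / n
    thr <- vapply(lambda, poissonThreshold, integer(1), level = level)
    keep <- rep(FALSE, n)
    for (s in seq_len(ncol(counts)))
        keep <- keep | counts[, s] >= thr[s]
    names(keep) <- NULL
    new("PoissonFilterResult",
        retained = which(keep),
        lambda = setNames(as.numeric(lambda), colnames(counts)),
        threshold = setNames(as.integer(thr), colnames(counts)),
        alpha = alpha, nWindows = as.integer(n))
}

#' Write a window count matrix as TSV
#'
#' BED-style coordinates (0-based half-open \code{start}, \code{end})
#' followed by one integer column per sample.
#'
#' @param x a \linkS4class{WindowCounts}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCountsTsv <- function(x, path) {
    gr <- rowRanges(x)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     as.data.frame(assay(x, "counts")),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a window count matrix from TSV
#'
#' @param path counts TSV written by [writeCountsTsv()].
#' @param group group labels, one per sample column.
#' @param chromSizes optional \code{Seqinfo} or named lengths; inferred from
#'   the maximal end per chromosome when absent.
#' @return a \linkS4class{WindowCounts}.
#' @export
readCountsTsv <- function(path, group, chromSizes = NULL) {
    df <- read.delim(path, check.names = FALSE)
    if (!all(c("chrom", "start", "end") %in% colnames(df)))
        stop("counts TSV must have chrom, start, end columns")
    samples <- setdiff(colnames(df), c("chrom", "start", "end"))
    if (is.null(chromSizes)) {
        sl <- vapply(split(df$end, df$chrom), max, numeric(1))
        chromSizes <- Seqinfo(names(sl), as.integer(sl))
    } else if (!is(chromSizes, "Seqinfo")) {
        chromSizes <- Seqinfo(names(chromSizes), as.integer(chromSizes))
    }
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  seqinfo = chromSizes)
    WindowCounts(as.matrix(df[, samples, drop = FALSE]), gr, group)
}

#' Write the filter report as TSV
#' @param fr a \linkS4class{PoissonFilterResult}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFilterReport <- function(fr, path) {
    df <- data.frame(sample = names(fr@lambda),
                     lambda = fr@lambda, threshold = fr@threshold,
                     row.names = NULL)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
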