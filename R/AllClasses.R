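#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#'   queryHits subjectHits
#' @importFrom IRanges IRanges IRangesList IntegerList coverage
#'   overlapsAny shift
#' @importFrom GenomicRanges GRanges granges seqnames strand strand<- start
#'   end width resize trim findOverlaps countOverlaps distanceToNearest
#'   reduce promoters tileGenome GRangesList binnedAverage
#' @importFrom BiocGenerics sort
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo seqinfo<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges
#' @importFrom stats dpois ppois qpois rpois runif rnorm rmultinom quantile
#'   p.adjust t.test var setNames coef
#' @importFrom utils read.delim write.table
NULL

#' WindowCounts: window-level coverage counts across samples
#'
#' A thin extension of \linkS4class{RangedSummarizedExperiment} holding the
#' rounded average per-base coverage of every fixed-width window tiling the
#' genome (rows) for every sample (columns).  \code{rowRanges()} is the window
#' grid; \code{colData()} carries the sample \code{group} factor and, when the
#' object comes from the simulator, the true library \code{sizeFactor}.
#'
#' Counts must be non-negative and integer-valued.  The window grid tiles each
#' chromosome completely: all windows share the nominal width except possibly
#' the last window of a chromosome, which may be truncated.
#'
#' @seealso [tileWindows()], [countCoverage()], [simulateCounts()]
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

.validWindowCounts <- function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        x <- assay(object, "counts")
        if (any(x < 0) || any(x != round(x)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must carry a 'group' column")
    if (is.null(msg)) TRUE else msg
}
setValidity("WindowCounts", .validWindowCounts)

#' Construct a WindowCounts object
#'
#' @param counts integer matrix, windows x samples.
#' @param grid a \code{GRanges} window grid, one range per row of
#'   \code{counts}, as produced by [tileWindows()].
#' @param group factor or character vector of group labels, one per sample.
#' @param sizeFactor optional numeric vector of per-sample library-size
#'   multipliers (informational; stored in \code{colData}).
#' @return a \linkS4class{WindowCounts} object.
#' @export
WindowCounts <- function(counts, grid, group, sizeFactor = NULL) {
    counts <- as.matrix(counts)
    if (length(grid) != nrow(counts))
        stop("length(grid) must equal nrow(counts)")
    if (length(group) != ncol(counts))
        stop("length(group) must equal ncol(counts)")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    cd <- DataFrame(group = factor(group), row.names = colnames(counts))
    if (!is.null(sizeFactor)) cd$sizeFactor <- sizeFactor
    storage.mode(counts) <- "integer"
    new("WindowCounts", SummarizedExperiment(
        assays = list(counts = counts), rowRanges = grid, colData = cd))
}

#' Sample group labels of a WindowCounts object
#' @param x a \linkS4class{WindowCounts} object.
#' @return the \code{group} factor from \code{colData(x)}.
#' @export
sampleGroups <- function(x) colData(x)$group

#' PoissonFilterResult: outcome of the even-coverage window filter
#'
#' Records, per sample, the genome-wide mean count under the even-coverage
#' assumption (\code{lambda}), the minimal count significant at the
#' Bonferroni-corrected level (\code{threshold}), and the indices of windows
#' retained because at least one sample reached its threshold.
#'
#' @slot retained integer indices of retained windows.
#' @slot lambda named numeric, per-sample even-coverage rate estimate.
#' @slot threshold named integer, per-sample minimal significant count.
#' @slot alpha the family-wise level used.
#' @slot nWindows total number of windows tested.
#' @seealso [poissonFilter()]
#' @export
setClass("PoissonFilterResult", representation(
    retained  = "integer",
    lambda    = "numeric",
    threshold = "integer",
    alpha     = "numeric",
    nWindows  = "integer"))

setValidity("PoissonFilterResult", function(object) {
    msg <- NULL
    if (any(object@threshold < 1L))
        msg <- c(msg, "thresholds must be >= 1")
    if (length(object@retained) &&
        (min(object@retained) < 1L || max(object@retained) > object@nWindows))
        msg <- c(msg, "retained indices out of range")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PoissonFilterResult", function(object) {
    cat("PoissonFilterResult:", length(object@retained), "of",
        object@nWindows, "windows retained (alpha =", object@alpha, ")\n")
    cat("  per-sample lambda:",
        paste(sprintf("%s=%.3g", names(object@lambda), object@lambda),
              collapse = ", "), "\n")
    cat("  per-sample threshold:",
        paste(sprintf("%s=%d", names(object@threshold), object@threshold),
              collapse = ", "), "\n")
})

#' Retained window indices of a filter result
#' @param x a \linkS4class{PoissonFilterResult}.
#' @return integer vector of retained window indices.
#' @export
retainedWindows <- function(x) x@retained

#' Per-sample filter rate estimates
#' @param x a \linkS4class{PoissonFilterResult}.
#' @return named numeric vector of even-coverage rate estimates.
#' @export
filterRates <- function(x) x@lambda

#' Per-sample filter count thresholds
#' @param x a \linkS4class{PoissonFilterResult}.
#' @return named integer vector of minimal significant counts.
#' @export
filterThresholds <- function(x) x@threshold

#' ThreePoissonFit: a three-component Poisson mixture fitted to one sample
#'
#' Holds the maximum a posteriori mixture parameters estimated by EM from the
#' retained window counts of one sample, with the rates relabelled in
#' ascending order so that component 3 is the methylated (highest-rate)
#' component.  The objective trace is the observed-data log-likelihood plus
#' the (weak) prior terms; EM guarantees it is non-decreasing.
#'
#' @slot lambda numeric(3), component rates, ascending.
#' @slot weights numeric(3), mixing proportions, summing to 1.
#' @slot objective numeric, per-iteration penalised log-likelihood trace.
#' @slot converged logical, whether the relative change fell below tol.
#' @slot nIter number of EM iterations run.
#' @slot degenerate logical, TRUE when the data could not support three
#'   distinct components (fewer than 3 distinct count values).
#' @seealso [fitThreePoisson()], [methylationProbability()]
#' @export
setClass("ThreePoissonFit", representation(
    lambda     = "numeric",
    weights    = "numeric",
    objective  = "numeric",
    converged  = "logical",
    nIter      = "integer",
    degenerate = "logical"))

setValidity("ThreePoissonFit", function(object) {
    msg <- NULL
    if (length(object@lambda) != 3L || length(object@weights) != 3L)
        msg <- c(msg, "lambda and weights must have length 3")
    if (is.unsorted(object@lambda))
        msg <- c(msg, "lambda must be ascending")
    if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative and sum to 1")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ThreePoissonFit", function(object) {
    cat("ThreePoissonFit (",
        if (object@converged) "converged" else "not converged",
        " in ", object@nIter, " iterations",
        if (object@degenerate) ", degenerate" else "", ")\n", sep = "")
    cat(sprintf("  lambda: %.4g  %.4g  %.4g\n",
                object@lambda[1], object@lambda[2], object@lambda[3]))
    cat(sprintf("  weights: %.4g  %.4g  %.4g\n",
                object@weights[1], object@weights[2], object@weights[3]))
})

#' Component rates of a mixture fit
#' @param x a \linkS4class{ThreePoissonFit}.
#' @return numeric(3) of ascending Poisson rates.
#' @export
mixtureRates <- function(x) x@lambda

#' Mixing weights of a mixture fit
#' @param x a \linkS4class{ThreePoissonFit}.
#' @return numeric(3) of mixing proportions.
#' @export
mixtureWeights <- function(x) x@weights

#' MethylationTruth: planted ground truth for synthetic data
#'
#' The simulator's record of what was planted: the truth regions with their
#' per-group Poisson rates, the per-sample library size factors, the planted
#' differential-expression table, and the subset of genes whose promoter
#' overlaps a sharp region of opposite direction (the inverse-correlation
#' genes every downstream validation compares against).
#'
#' @slot regions \code{GRanges} with metadata columns \code{kind}
#'   (\code{shared_methylated}, \code{sharp01}, \code{sharp10},
#'   \code{quantitative}), \code{rateA}, \code{rateB}, and \code{gene} (the
#'   designated gene id for promoter-planted regions, NA otherwise).
#' @slot sizeFactors named positive numeric, one per sample.
#' @slot deTable data.frame of planted DE genes: \code{gene},
#'   \code{foldChange} (linear, group B over group A) and \code{padj}
#'   surrogate.
#' @slot inverseGenes character, planted inverse-correlation gene ids.
#' @slot backgroundRate numeric, the rate of every unplanted window.
#' @seealso [plantTruth()], [simulateCounts()], [simulateExpression()]
#' @export
setClass("MethylationTruth", representation(
    regions        = "GRanges",
    sizeFactors    = "numeric",
    deTable        = "data.frame",
    inverseGenes   = "character",
    backgroundRate = "numeric"))

.validTruth <- function(object) {
    msg <- NULL
    r <- object@regions
    need <- c("kind", "rateA", "rateB")
    if (!all(need %in% colnames(mcols(r))))
        return("regions need metadata columns kind, rateA, rateB")
    if (length(r) > 1L && any(countOverlaps(r, r) > 1L))
        msg <- c(msg, "truth regions must not overlap")
    if (any(mcols(r)$rateA < 0) || any(mcols(r)$rateB < 0))
        msg <- c(msg, "rates must be non-negative")
    if (any(object@sizeFactors <= 0))
        msg <- c(msg, "size factors must be positive")
    if (!all(object@inverseGenes %in% object@deTable$gene))
        msg <- c(msg, "inverse genes must be a subset of planted DE genes")
    bad <- mcols(r)$kind == "sharp01" & mcols(r)$rateB <= mcols(r)$rateA
    if (any(bad)) msg <- c(msg, "sharp01 regions require rateB > rateA")
    bad <- mcols(r)$kind == "sharp10" & mcols(r)$rateA <= mcols(r)$rateB
    if (any(bad)) msg <- c(msg, "sharp10 regions require rateA > rateB")
    if (is.null(msg)) TRUE else msg
}
setValidity("MethylationTruth", .validTruth)

setMethod("show", "MethylationTruth", function(object) {
    k <- table(mcols(object@regions)$kind)
    cat("MethylationTruth:", length(object@regions), "planted regions (",
        paste(sprintf("%s=%d", names(k), as.integer(k)), collapse = ", "),
        ")\n")
    cat("  background rate:", object@backgroundRate,
        "| samples:", length(object@sizeFactors),
        "| DE genes:", nrow(object@deTable),
        "| inverse genes:", length(object@inverseGenes), "\n")
})

#' Planted truth regions
#' @param x a \linkS4class{MethylationTruth}.
#' @return \code{GRanges} of planted regions with kind and rates.
#' @export
truthRegions <- function(x) x@regions

#' Planted per-sample size factors
#' @param x a \linkS4class{MethylationTruth}.
#' @return named numeric vector of library-size multipliers.
#' @export
truthSizeFactors <- function(x) x@sizeFactors

#' Planted differential-expression table
#' @param x a \linkS4class{MethylationTruth}.
#' @return data.frame of planted DE genes with fold changes.
#' @export
truthDETable <- function(x) x@deTable

#' Planted inverse-correlation gene ids
#' @param x a \linkS4class{MethylationTruth}.
#' @return character vector of gene ids.
#' @export
truthInverseGenes <- function(x) x@inverseGenes
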