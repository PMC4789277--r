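#' Mixed-effects differential test for one candidate region
#'
#' Models the log2(count + 1) of every (window, sample) pair in the
#' candidate with a fixed group effect and a random per-sample intercept
#' (the sample intercept absorbs library-size and biological sample-to-sample
#' variation).  The reported p-value is the Satterthwaite-df t-test on the
#' group term; when the mixed fit is singular (random-effect variance at
#' zero) or fails, the test falls back to a Welch t-test on the per-sample
#' region means of the transformed counts, and the result is flagged.
#'
#' The fold change is reported on the linear count scale as
#' (meanB + pseudocount) / (meanA + pseudocount) of per-sample region-mean
#' raw counts, group B over group A.
#'
#' @param windows integer indices of the candidate's windows.
#' @param counts integer matrix, windows x samples (full grid).
#' @param group factor of sample group labels with exactly 2 levels; the
#'   second level is treated as group B (numerator of the fold change).
#' @param pseudocount added to both group means for the fold change
#'   (default 0.5).
#' @return list with \code{foldChange}, \code{pRaw}, \code{meanA},
#'   \code{meanB}, \code{fallback} (TRUE when Welch was used).
#' @export
testRegion <- function(windows, counts, group, pseudocount = 0.5) {
    group <- factor(group)
    if (nlevels(group) != 2L) stop("exactly two groups are required")
    if (any(table(group) < 1L)) stop("each group needs at least one sample")
    if (length(windows) < 1L) stop("candidate must contain at least one window")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    sub <- counts[windows, , drop = FALSE]
    y <- log2(sub + 1)
    sampleMeans <- colMeans(y)
    rawMeans <- colMeans(sub)
    isB <- group == levels(group)[2L]
    meanA <- mean(rawMeans[!isB])
    meanB <- mean(rawMeans[isB])
    fold <- (meanB + pseudocount) / (meanA + pseudocount)

    welch <- function() {
        a <- sampleMeans[!isB]; b <- sampleMeans[isB]
        if (var(a) + var(b) < .Machine$double.eps) {
            # no within-group variability at all: p is 1 when the group
            # means agree, effectively 0 when they differ
            return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
        }
        t.test(b, a)$p.value
    }

    p <- NA_real_
    fallback <- TRUE
    if (length(windows) >= 2L && min(table(group)) >= 2L) {
        df <- data.frame(y = as.vector(y),
                         sample = rep(colnames(counts), each = length(windows)),
                         group = rep(group, each = length(windows)))
        fit <- tryCatch(
            suppressMessages(suppressWarnings(
                lmerTest::lmer(y ~ group + (1 | sample), data = df))),
            error = function(e) NULL)
        if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
            co <- tryCatch(stats::coef(summary(fit)),
                           error = function(e) NULL)
            if (!is.null(co) && nrow(co) >= 2L &&
                is.finite(co[2L, "Pr(>|t|)"])) {
                p <- co[2L, "Pr(>|t|)"]
                fallback <- FALSE
            }
        }
    }
    if (fallback) p <- welch()
    list(foldChange = fold, pRaw = p, meanA = meanA, meanB = meanB,
         fallback = fallback)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up with monotonicity enforcement, as implemented by
#' \code{stats::p.adjust}; inputs are validated to lie in [0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return numeric vector of adjusted p-values.
#' @export
adjustPvalues <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Classify a significant candidate as sharp or quantitative
#'
#' A candidate below the FDR threshold is a sharp DMR when all samples of
#' one group are predicted methylated and all samples of the other
#' unmethylated (direction 01 = hypermethylated in group B, 10 =
#' hypomethylated in group B), and a quantitative DMR when all samples of
#' both groups are methylated but the counts differ.  Mixed status patterns
#' fit neither definition and are excluded with reason "inconsistent".
#'
#' @param status logical vector of per-sample methylation statuses over the
#'   candidate.
#' @param group factor of sample groups (second level = group B).
#' @param foldChange linear fold change (B over A) from [testRegion()].
#' @param pAdj BH-adjusted p-value.
#' @param fdr FDR threshold (default 0.05).
#' @return list with \code{call} in \{"sharp", "quantitative", "none"\},
#'   \code{direction} in \{"01", "10", NA\}, and \code{reason} in
#'   \{"ok", "not_significant", "inconsistent", "all_unmethylated"\}.
#' @export
classifyDmr <- function(status, group, foldChange, pAdj, fdr = 0.05) {
    group <- factor(group)
    isB <- group == levels(group)[2L]
    a <- status[!isB]; b <- status[isB]
    if (pAdj >= fdr)
        return(list(call = "none", direction = NA_character_,
                    reason = "not_significant"))
    if (all(b) && !any(a))
        return(list(call = "sharp", direction = "01", reason = "ok"))
    if (all(a) && !any(b))
        return(list(call = "sharp", direction = "10", reason = "ok"))
    if (all(a) && all(b))
        return(list(call = "quantitative",
                    direction = if (foldChange > 1) "01" else "10",
                    reason = "ok"))
    if (!any(a) && !any(b))
        return(list(call = "none", direction = NA_character_,
                    reason = "all_unmethylated"))
    list(call = "none", direction = NA_character_, reason = "inconsistent")
}

#' Test, adjust and classify all candidate regions
#'
#' Runs [testRegion()] on every candidate, BH-adjusts the p-values across
#' candidates, and classifies each significant candidate.  Returns all
#' candidates with their test results; emitted DMRs are the subset with
#' \code{call != "none"}.
#'
#' @param candidates \code{GRanges} from [candidateRegions()].
#' @param x a \linkS4class{WindowCounts}.
#' @param fdr FDR threshold on adjusted p-values (default 0.05).
#' @param pseudocount fold-change pseudocount (default 0.5).
#' @return \code{GRanges} of candidates with metadata columns
#'   \code{foldChange}, \code{pRaw}, \code{pAdj}, \code{call},
#'   \code{direction}, \code{reason}, \code{fallback}, \code{nWindows},
#'   plus the status matrix.
#' @export
testCandidates <- function(candidates, x, fdr = 0.05, pseudocount = 0.5) {
    counts <- assay(x, "counts")
    group <- sampleGroups(x)
    n <- length(candidates)
    if (n == 0L) {
        mcols(candidates)$foldChange <- numeric(0)
        mcols(candidates)$pRaw <- numeric(0)
        mcols(candidates)$pAdj <- numeric(0)
        mcols(candidates)$call <- character(0)
        mcols(candidates)$direction <- character(0)
        mcols(candidates)$reason <- character(0)
        mcols(candidates)$fallback <- logical(0)
        return(candidates)
    }
    res <- lapply(seq_len(n), function(i)
        testRegion(mcols(candidates)$windows[[i]], counts, group,
                   pseudocount))
    fold <- vapply(res, `[[`, numeric(1), "foldChange")
    pRaw <- vapply(res, `[[`, numeric(1), "pRaw")
    pAdj <- adjustPvalues(pRaw)
    st <- mcols(candidates)$status
    cls <- lapply(seq_len(n), function(i)
        classifyDmr(st[i, ], group, fold[i], pAdj[i], fdr))
    mcols(candidates)$foldChange <- fold
    mcols(candidates)$pRaw <- pRaw
    mcols(candidates)$pAdj <- pAdj
    mcols(candidates)$call <- vapply(cls, `[[`, character(1), "call")
    mcols(candidates)$direction <- vapply(cls, `[[`, character(1), "direction")
    mcols(candidates)$reason <- vapply(cls, `[[`, character(1), "reason")
    mcols(candidates)$fallback <- vapply(res, `[[`, logical(1), "fallback")
    candidates
}

#' Extract the emitted DMRs from tested candidates
#'
#' @param tested \code{GRanges} from [testCandidates()].
#' @param class optional filter: "sharp", "quantitative" or NULL for both.
#' @return \code{GRanges} of DMRs.
#' @export
dmrRegions <- function(tested, class = NULL) {
    keep <- mcols(tested)$call != "none"
    if (!is.null(class)) keep <- keep & mcols(tested)$call %in% class
    tested[keep]
}

#' Window-normalised square-root count matrix for heatmap display
#'
#' For each DMR and sample: the square root of the DMR's total read count
#' divided by its number of windows, i.e. sqrt(mean count per window).
#' Zero counts map to 0.
#'
#' @param dmrs \code{GRanges} of DMRs carrying a \code{windows} column.
#' @param x a \linkS4class{WindowCounts}.
#' @return numeric matrix, DMRs x samples.
#' @export
heatmapMatrix <- function(dmrs, x) {
    counts <- assay(x, "counts")
    m <- t(vapply(seq_along(dmrs), function(i) {
        w <- mcols(dmrs)$windows[[i]]
        sqrt(colSums(counts[w, , drop = FALSE]) / length(w))
    }, numeric(ncol(counts))))
    if (length(dmrs) == 0L)
        m <- matrix(0, 0L, ncol(counts), dimnames = list(NULL, colnames(counts)))
    rownames(m) <- mcols(dmrs)$candidate
    m
}

#' Per-chromosome counts of hyper- and hypomethylated DMRs
#'
#' @param dmrs \code{GRanges} of DMRs with a \code{direction} column
#'   ("01" = hyper in group B, "10" = hypo in group B).
#' @return data.frame with columns \code{chrom}, \code{hyper}, \code{hypo}.
#' @export
countByChromosome <- function(dmrs) {
    chrom <- as.character(seqnames(dmrs))
    lev <- seqlevels(dmrs)
    hyper <- table(factor(chrom[mcols(dmrs)$direction == "01"], levels = lev))
    hypo <- table(factor(chrom[mcols(dmrs)$direction == "10"], levels = lev))
    data.frame(chrom = lev, hyper = as.integer(hyper),
               hypo = as.integer(hypo), row.names = NULL)
}

#' Write the tested-candidate / DMR table as TSV
#'
#' @param tested \code{GRanges} from [testCandidates()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDmrTable <- function(tested, path) {
    st <- mcols(tested)$status
    df <- data.frame(chrom = as.character(seqnames(tested)),
                     start = start(tested) - 1L, end = end(tested),
                     candidate = mcols(tested)$candidate,
                     call = mcols(tested)$call,
                     direction = mcols(tested)$direction,
                     foldChange = mcols(tested)$foldChange,
                     pRaw = mcols(tested)$pRaw,
                     pAdj = mcols(tested)$pAdj,
                     nWindows = mcols(tested)$nWindows,
                     reason = mcols(tested)$reason,
                     stringsAsFactors = FALSE)
    if (!is.null(st)) {
        stDf <- as.data.frame(st + 0L)
        colnames(stDf) <- paste0("status_", colnames(st))
        df <- cbind(df, stDf)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
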