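#' Read and validate a differential-expression table
#'
#' Expects a TSV with columns \code{gene}, \code{fold_change} (linear,
#' group B over group A) and \code{padj}.  Rows with missing or invalid
#' values are rejected with their line numbers; duplicated gene ids are an
#' error because the promoter-DMR join would be ambiguous.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{gene}, \code{foldChange},
#'   \code{padj}.
#' @export
readExpressionTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "fold_change", "padj")
    if (!all(need %in% colnames(df)))
        stop("expression table must have columns: ",
             paste(need, collapse = ", "))
    fc <- suppressWarnings(as.numeric(df$fold_change))
    padj <- suppressWarnings(as.numeric(df$padj))
    bad <- which(is.na(df$gene) | df$gene == "" |
                 is.na(fc) | fc <= 0 |
                 is.na(padj) | padj < 0 | padj > 1)
    if (length(bad))
        stop("invalid expression rows at line(s): ",
             paste(bad + 1L, collapse = ", "),
             " (need gene, fold_change > 0, padj in [0, 1])")
    if (anyDuplicated(df$gene))
        stop("duplicated gene id(s): ",
             paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
    data.frame(gene = df$gene, foldChange = fc, padj = padj,
               stringsAsFactors = FALSE)
}

#' Join promoter sharp DMRs with differential expression
#'
#' The gene-level integration: keep genes that (i) have at least one sharp
#' DMR whose priority category is promoter and (ii) are differentially
#' expressed at \code{deAlpha}.  A gene is inversely correlated when its
#' promoter is hypermethylated (01) and its expression falls (fold change
#' < 1), or hypomethylated (10) and its expression rises (fold change > 1).
#' Genes whose promoter DMRs disagree in direction are marked discordant
#' and never flagged inverse.
#'
#' @param annotated \code{GRanges} of annotated DMRs from [annotateDmrs()];
#'   only rows with \code{call == "sharp"} and \code{category ==
#'   "promoter"} participate.
#' @param genes gene models (\code{GRanges} with \code{name}), used to
#'   resolve which gene's promoter each DMR overlaps.
#' @param expression data.frame from [readExpressionTable()].
#' @param deAlpha adjusted-p threshold for differential expression
#'   (default 0.05).
#' @param upstream,downstream promoter extent, as used in annotation.
#' @return data.frame sorted by gene: \code{gene}, \code{methDirection}
#'   ("01", "10" or "discordant"), \code{exprFoldChange}, \code{exprPadj},
#'   \code{exprDirection} ("up"/"down"), \code{inverse} (logical),
#'   \code{dmrCoords} (comma-separated chrom:start-end, 0-based half-open).
#' @export
integrateExpression <- function(annotated, genes, expression,
                                deAlpha = 0.05, upstream = 1000L,
                                downstream = 500L) {
    if ("fold_change" %in% colnames(expression) &&
        !"foldChange" %in% colnames(expression))
        colnames(expression)[colnames(expression) == "fold_change"] <-
            "foldChange"
    sharpProm <- annotated[mcols(annotated)$call == "sharp" &
                           mcols(annotated)$category == "promoter"]
    empty <- data.frame(gene = character(0), methDirection = character(0),
                        exprFoldChange = numeric(0), exprPadj = numeric(0),
                        exprDirection = character(0), inverse = logical(0),
                        dmrCoords = character(0), stringsAsFactors = FALSE)
    if (length(sharpProm) == 0L || nrow(expression) == 0L) return(empty)
    geneIds <- mcols(genes)$name
    prom <- promoterInterval(genes, upstream, downstream)
    hits <- findOverlaps(sharpProm, prom, ignore.strand = TRUE)
    if (length(hits) == 0L) return(empty)
    perGene <- split(queryHits(hits), geneIds[subjectHits(hits)])
    rows <- lapply(names(perGene), function(g) {
        e <- expression[expression$gene == g, , drop = FALSE]
        if (nrow(e) == 0L || e$padj >= deAlpha) return(NULL)
        idx <- perGene[[g]]
        dirs <- unique(mcols(sharpProm)$direction[idx])
        methDir <- if (length(dirs) > 1L) "discordant" else dirs
        exprDir <- if (e$foldChange > 1) "up" else "down"
        inv <- (methDir == "01" && e$foldChange < 1) ||
               (methDir == "10" && e$foldChange > 1)
        coords <- paste(sprintf("%s:%d-%d",
                                as.character(seqnames(sharpProm))[idx],
                                start(sharpProm)[idx] - 1L,
                                end(sharpProm)[idx]),
                        collapse = ",")
        data.frame(gene = g, methDirection = methDir,
                   exprFoldChange = e$foldChange, exprPadj = e$padj,
                   exprDirection = exprDir, inverse = inv,
                   dmrCoords = coords, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    out[order(out$gene), , drop = FALSE]
}
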