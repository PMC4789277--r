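#' Default pipeline configuration
#'
#' One flat, documented profile holding every tunable of the pipeline:
#' 50-bp windows; Bonferroni-corrected filter level 0.05; mixture EM
#' tolerances; scan gap/length limits; FDR 0.05 for DMRs; promoter
#' 1000/500 bp, 3' end +/- 1000 bp, CGI shore/shelf bands of 2000 bp; DE
#' adjusted-p threshold 0.05.  \code{runPipeline()} rejects configs with
#' unknown keys, so typos cannot silently fall back to defaults.
#'
#' @param ... overrides of the defaults, by name.
#' @return named list of settings.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        window = 50L,
        filterAlpha = 0.05,
        emMaxIter = 500L, emTol = 1e-8,
        emWeightFloor = 1e-6, emRateFloor = 1e-6,
        tau = 0.5,
        maxGap = 2L, minWindows = 2L, majority = 0.5,
        fdr = 0.05, pseudocount = 0.5,
        promoterUpstream = 1000L, promoterDownstream = 500L,
        threePrimeFlank = 1000L,
        shoreWidth = 2000L, shelfWidth = 2000L,
        deAlpha = 0.05,
        writePosteriors = FALSE,
        seed = 1L)
    override <- list(...)
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(override)] <- override
    .checkConfig(cfg)
    cfg
}

.checkConfig <- function(cfg) {
    with(cfg, {
        stopifnot(window >= 1, filterAlpha > 0, filterAlpha < 1,
                  emMaxIter >= 1, emTol > 0, tau > 0, tau < 1,
                  maxGap >= 0, minWindows >= 1,
                  majority > 0, majority <= 1,
                  fdr > 0, fdr < 1, pseudocount >= 0,
                  promoterUpstream >= 0, promoterDownstream >= 0,
                  threePrimeFlank >= 0, shoreWidth >= 0, shelfWidth >= 0,
                  deAlpha > 0, deAlpha < 1)
    })
    invisible(cfg)
}

#' Run the full differential-methylation pipeline
#'
#' Executes filter -> mixture fit -> posterior/status -> scan -> candidate
#' unification -> mixed-model testing -> classification -> annotation ->
#' expression integration on an in-memory \linkS4class{WindowCounts}
#' object, writing every stage table into \code{outdir} together with a
#' manifest (config echo, per-stage row counts, md5 checksum of every
#' output).  Identical inputs and config give byte-identical outputs.
#'
#' @param x a \linkS4class{WindowCounts} (e.g. from [countCoverage()],
#'   [readCountsTsv()] or [simulateCounts()]).
#' @param genes gene models (\code{GRanges}); may be empty.
#' @param islands CpG islands (\code{GRanges}); may be empty.
#' @param expression DE table (data.frame with \code{gene},
#'   \code{foldChange}, \code{padj}), or NULL to skip integration.
#' @param outdir output directory, created if needed.
#' @param config list from [pipelineConfig()].
#' @return (invisibly) a list with the stage results: \code{filter},
#'   \code{fits}, \code{segments}, \code{candidates}, \code{tested},
#'   \code{dmrs} (annotated), \code{heatmap}, \code{chromSummary},
#'   \code{integration}, \code{manifest}.
#' @export
runPipeline <- function(x, genes, islands, expression = NULL,
                        outdir = tempfile("mbdscan_run_"),
                        config = pipelineConfig()) {
    .checkConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log <- function(stage, ...) message("[", stage, "] ", ...)
    paths <- character(0)
    put <- function(name, writer) {
        p <- file.path(outdir, name)
        writer(p)
        paths[[name]] <<- p
        p
    }

    filt <- poissonFilter(x, alpha = config$filterAlpha)
    log("filter", length(retainedWindows(filt)), " of ", nrow(x),
        " windows retained")
    put("filter_report.tsv", function(p) writeFilterReport(filt, p))

    ret <- retainedWindows(filt)
    if (length(ret)) {
        fits <- fitSamples(x, windows = ret,
                           maxIter = config$emMaxIter, tol = config$emTol,
                           weightFloor = config$emWeightFloor,
                           rateFloor = config$emRateFloor)
        post <- posteriorMatrix(x, fits, retained = ret, filter = filt)
    } else {
        fits <- structure(list(), names = character(0))
        post <- matrix(0, nrow(x), ncol(x),
                       dimnames = dimnames(assay(x, "counts")))
    }
    log("fit", sum(vapply(fits, slot, logical(1), "converged")), " of ",
        length(fits), " sample fits converged")
    put("fit_report.tsv", function(p) writeFitReport(fits, p))
    status <- callStatus(post, tau = config$tau)
    if (isTRUE(config$writePosteriors))
        put("posteriors.tsv", function(p) {
            gr <- rowRanges(x)
            df <- data.frame(chrom = as.character(seqnames(gr)),
                             start = start(gr) - 1L, end = end(gr),
                             round(post, 6), check.names = FALSE)
            write.table(df, p, sep = "\t", quote = FALSE,
                        row.names = FALSE)
        })

    segs <- scanSegments(status, rowRanges(x), maxGap = config$maxGap,
                         minWindows = config$minWindows)
    log("scan", length(segs), " per-sample segments")
    put("segments.bed", function(p) .writeBed6(
        segs, p, name = mcols(segs)$sample, score = mcols(segs)$nMeth))

    cand <- candidateRegions(segs, status, rowRanges(x),
                             majority = config$majority)
    log("candidates", length(cand), " candidate regions")
    put("candidate_status.tsv", function(p) {
        st <- mcols(cand)$status
        df <- data.frame(candidate = mcols(cand)$candidate,
                         chrom = as.character(seqnames(cand)),
                         start = start(cand) - 1L, end = end(cand))
        if (length(cand)) df <- cbind(df, as.data.frame(st + 0L))
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })

    tested <- testCandidates(cand, x, fdr = config$fdr,
                             pseudocount = config$pseudocount)
    dmrs <- dmrRegions(tested)
    log("test", length(dmrs), " DMRs (",
        sum(mcols(dmrs)$call == "sharp"), " sharp, ",
        sum(mcols(dmrs)$call == "quantitative"), " quantitative)")
    put("dmr_table.tsv", function(p) writeDmrTable(tested, p))

    sharp <- dmrRegions(tested, "sharp")
    hm <- heatmapMatrix(sharp, x)
    put("heatmap_matrix.tsv", function(p) {
        df <- data.frame(candidate = rownames(hm), round(hm, 6),
                         check.names = FALSE)
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    chromSummary <- countByChromosome(sharp)
    put("chromosome_summary.tsv", function(p)
        write.table(chromSummary, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))

    annotated <- annotateDmrs(dmrs, genes, islands,
                              upstream = config$promoterUpstream,
                              downstream = config$promoterDownstream,
                              threePrimeFlank = config$threePrimeFlank)
    put("dmr_annotated.tsv", function(p) {
        df <- data.frame(chrom = as.character(seqnames(annotated)),
                         start = start(annotated) - 1L,
                         end = end(annotated),
                         candidate = mcols(annotated)$candidate,
                         call = mcols(annotated)$call,
                         direction = mcols(annotated)$direction,
                         foldChange = mcols(annotated)$foldChange,
                         pAdj = mcols(annotated)$pAdj,
                         category = mcols(annotated)$category,
                         cgiContext = mcols(annotated)$cgiContext,
                         cgiDistance = mcols(annotated)$cgiDistance,
                         overlapGenes = mcols(annotated)$overlapGenes)
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    sharpAnn <- annotated[mcols(annotated)$call == "sharp"]
    props <- contextProportions(mcols(sharpAnn)$category,
                                mcols(sharpAnn)$direction)
    put("context_proportions.tsv", function(p)
        write.table(props, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))

    integration <- NULL
    if (!is.null(expression)) {
        integration <- integrateExpression(
            annotated, genes, expression, deAlpha = config$deAlpha,
            upstream = config$promoterUpstream,
            downstream = config$promoterDownstream)
        log("integrate", sum(integration$inverse), " inverse genes of ",
            nrow(integration), " promoter-DMR DE genes")
        put("integration.tsv", function(p)
            write.table(integration, p, sep = "\t", quote = FALSE,
                        row.names = FALSE))
    }

    manifest <- c(
        list(package = "MBDscan",
             stages = list(
                 windowsTotal = nrow(x),
                 windowsRetained = length(retainedWindows(filt)),
                 segments = length(segs),
                 candidates = length(cand),
                 dmrs = length(dmrs),
                 sharp = length(sharp),
                 integrationRows = if (is.null(integration)) 0L
                                   else nrow(integration))),
        list(config = config),
        list(checksums = as.list(tools::md5sum(unlist(paths)))))
    manifestPath <- file.path(outdir, "manifest.dcf")
    .writeManifest(manifest, manifestPath)

    invisible(list(filter = filt, fits = fits, segments = segs,
                   candidates = cand, tested = tested, dmrs = annotated,
                   heatmap = hm, chromSummary = chromSummary,
                   integration = integration, manifest = manifest,
                   outdir = outdir))
}

.writeManifest <- function(manifest, path) {
    flat <- unlist(manifest)
    writeLines(paste0(names(flat), ": ", as.character(flat)), path)
    invisible(path)
}

.writeBed6 <- function(gr, path, name = ".", score = 0L) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = name, score = score,
                     strand = ifelse(as.character(strand(gr)) == "*", ".",
                                     as.character(strand(gr))))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write a synthetic input bundle to disk
#'
#' Generates a toy genome, annotations, planted truth, counts and a DE
#' table, and writes them in standard formats: chrom sizes TSV, counts
#' TSV, truth BED6, genes BED12, islands BED3, expression TSV, design TSV.
#'
#' @param outdir output directory.
#' @param nChroms,chromLength genome shape.
#' @param nGenes,nIslands annotation sizes.
#' @param truthCfg list from [truthConfig()].
#' @param nA,nB samples per group.
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return (invisibly) list with the in-memory objects (\code{genome},
#'   \code{genes}, \code{islands}, \code{truth}, \code{counts},
#'   \code{expression}, \code{design}) and the file paths.
#' @export
simulateBundle <- function(outdir, nChroms = 2L, chromLength = 5e6,
                           nGenes = 50L, nIslands = 40L,
                           truthCfg = truthConfig(), nA = 3L, nB = 3L,
                           seed = 1L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    genome <- makeToyGenome(nChroms, chromLength)
    ann <- makeAnnotations(genome, nGenes, nIslands, seed = seed)
    design <- sampleDesign(nA, nB)
    truth <- plantTruth(genome, ann$genes, truthCfg,
                        nSamples = nA + nB, seed = seed + 1L)
    counts <- simulateCounts(genome, truth, design,
                             window = truthCfg$window, seed = seed + 2L)
    expr <- simulateExpression(ann$genes, truth, seed = seed + 3L)

    sizesPath <- file.path(outdir, "chrom_sizes.tsv")
    write.table(data.frame(chrom = seqlevels(genome),
                           length = unname(seqlengths(genome))),
                sizesPath, sep = "\t", quote = FALSE, row.names = FALSE)
    countsPath <- file.path(outdir, "counts.tsv")
    writeCountsTsv(counts, countsPath)
    truthPath <- file.path(outdir, "truth.bed")
    writeTruthBed(truth, truthPath)
    genesPath <- file.path(outdir, "genes.bed")
    if (length(ann$genes)) rtracklayer::export(ann$genes, genesPath,
                                               format = "bed")
    else file.create(genesPath)
    islandsPath <- file.path(outdir, "islands.bed")
    .writeBed3(ann$islands, islandsPath)
    exprPath <- file.path(outdir, "expression.tsv")
    write.table(expr, exprPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    designPath <- file.path(outdir, "design.tsv")
    write.table(design, designPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(genome = genome, genes = ann$genes,
                   islands = ann$islands, truth = truth, counts = counts,
                   expression = expr, design = design,
                   paths = list(sizes = sizesPath, counts = countsPath,
                                truth = truthPath, genes = genesPath,
                                islands = islandsPath,
                                expression = exprPath,
                                design = designPath)))
}

.writeBed3 <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read gene models from BED12
#'
#' @param path BED12 file.
#' @param genome optional \code{Seqinfo} to attach.
#' @return \code{GRanges} with \code{name} and \code{blocks} columns.
#' @export
readGenesBed <- function(path, genome = NULL) {
    if (file.size(path) == 0L) {
        gr <- GRanges(seqinfo = if (is.null(genome)) Seqinfo() else genome)
        mcols(gr)$name <- character(0)
        mcols(gr)$blocks <- IRanges::IRangesList()
        return(gr)
    }
    gr <- rtracklayer::import(path, format = "bed")
    if (!is.null(genome)) seqinfo(gr) <- genome[seqlevels(gr)]
    gr
}

#' Read CpG islands from BED3
#'
#' @param path BED file.
#' @param genome optional \code{Seqinfo} to attach.
#' @return \code{GRanges}.
#' @export
readIslandsBed <- function(path, genome = NULL) {
    if (file.size(path) == 0L)
        return(GRanges(seqinfo = if (is.null(genome)) Seqinfo() else genome))
    gr <- rtracklayer::import(path, format = "bed")
    if (!is.null(genome)) seqinfo(gr) <- genome[seqlevels(gr)]
    gr
}
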