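#' Fit a three-component Poisson mixture to one sample's window counts
#'
#' Window counts from an enrichment methylome experiment mix three signal
#' regimes: unmethylated background, ambient/intermediate signal, and
#' methylated enrichment.  The mixture is fitted by EM to a maximum a
#' posteriori estimate under weak conjugate priors (Gamma(1, 1e-3) on each
#' rate, symmetric Dirichlet(1) on the weights), which reduces to maximum
#' likelihood up to a negligible shrinkage of the rates.  Components are
#' relabelled so the rates are ascending; the highest-rate component is the
#' methylated one.
#'
#' Initialisation is deterministic (rates at the 25th/75th/99th percentiles
#' of the counts plus 0.1; weights 0.6/0.3/0.1), so identical inputs give
#' identical fits and the fit is invariant to the order of the counts.
#'
#' @param counts non-negative integer vector of window counts for one
#'   sample (typically the filter-retained windows).
#' @param maxIter maximum EM iterations (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-8).
#' @param weightFloor lower bound on mixing weights (default 1e-6).
#' @param rateFloor lower bound on rates (default 1e-6).
#' @return a \linkS4class{ThreePoissonFit}.  When the data hold fewer than
#'   three distinct count values the fit is flagged \code{degenerate} and
#'   carries as many effective components as the data support, the rest
#'   collapsing onto them.
#' @examples
#' set.seed(1)
#' x <- c(rpois(700, 0.2), rpois(200, 5), rpois(100, 25))
#' fitThreePoisson(x)
#' @export
fitThreePoisson <- function(counts, maxIter = 500L, tol = 1e-8,
                            weightFloor = 1e-6, rateFloor = 1e-6) {
    if (length(counts) == 0L) stop("no counts supplied")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    priorRate <- 1e-3   # Gamma(shape = 1, rate = priorRate) on each lambda

    tab <- table(counts)
    v <- as.numeric(names(tab))      # distinct count values
    nv <- as.numeric(tab)            # multiplicities
    degenerate <- length(v) < 3L
    if (degenerate)
        warning("fewer than 3 distinct count values; mixture components ",
                "will collapse (degenerate fit)")

    q <- as.numeric(quantile(counts, c(0.25, 0.75, 0.99))) + 0.1
    # strictly increasing starting rates even for ties in the quantiles
    lambda <- pmax(q + c(0, 1e-3, 2e-3) * (1 + q), rateFloor)
    pi <- c(0.6, 0.3, 0.1)

    obj <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    iter <- 0L
    N <- sum(nv)
    for (iter in seq_len(maxIter)) {
        ld <- vapply(seq_len(3L),
                     function(k) dpois(v, lambda[k], log = TRUE) + log(pi[k]),
                     numeric(length(v)))
        m <- apply(ld, 1L, max)
        lse <- m + log(rowSums(exp(ld - m)))
        r <- exp(ld - lse)           # responsibilities, rows sum to 1
        cur <- sum(nv * lse) - priorRate * sum(lambda)
        obj <- c(obj, cur)
        if (is.finite(prev) &&
            abs(cur - prev) < tol * (abs(prev) + .Machine$double.eps)) {
            converged <- TRUE
            break
        }
        prev <- cur
        Nk <- colSums(nv * r)
        pi <- pmax(Nk / N, weightFloor)
        pi <- pi / sum(pi)
        lambda <- pmax(colSums(nv * r * v) / (Nk + priorRate), rateFloor)
    }
    o <- order(lambda)
    new("ThreePoissonFit",
        lambda = lambda[o], weights = pi[o], objective = obj,
        converged = converged, nIter = iter, degenerate = degenerate)
}

#' Fit the mixture to every sample of a WindowCounts object
#'
#' @param x a \linkS4class{WindowCounts}.
#' @param windows indices of windows to fit on (typically
#'   \code{retainedWindows(poissonFilter(x))}); default all windows.
#' @param ... passed to [fitThreePoisson()].
#' @return named list of \linkS4class{ThreePoissonFit}, one per sample.
#' @export
fitSamples <- function(x, windows = seq_len(nrow(x)), ...) {
    counts <- assay(x, "counts")[windows, , drop = FALSE]
    fits <- lapply(seq_len(ncol(counts)),
                   function(s) fitThreePoisson(counts[, s], ...))
    names(fits) <- colnames(counts)
    fits
}

#' Posterior probability of methylation for given counts
#'
#' The posterior weight of the methylated (highest-rate) mixture component
#' at each count, computed in log space:
#' p = pi3 * Pois(c; lambda3) / sum_k pi_k * Pois(c; lambda_k).
#'
#' When the fitted data hold only two real signal regimes the two top
#' components collapse onto (nearly) the same rate and the likelihood
#' splits their weight arbitrarily.  Components whose rates sit within
#' \code{collapseSd} Poisson standard deviations of the top rate
#' (lambda3 - lambda_k <= collapseSd * sqrt(lambda3)) cannot be resolved
#' at single-window counting noise and are counted as part of the
#' methylated component, their posteriors added.  If all three components
#' have collapsed the data carry a single regime and only the top
#' component's (then constant) posterior is returned.
#'
#' @param fit a \linkS4class{ThreePoissonFit}.
#' @param counts integer vector of window counts.
#' @param collapseSd components within this many Poisson standard
#'   deviations of lambda3 are treated as methylated (default 2).
#' @return numeric vector of posteriors in [0, 1].
#' @export
methylationProbability <- function(fit, counts, collapseSd = 2) {
    post <- componentPosterior(fit, counts)
    top <- fit@lambda[3L] - fit@lambda <= collapseSd * sqrt(fit@lambda[3L])
    if (all(top)) top <- c(FALSE, FALSE, TRUE)
    rowSums(post[, top, drop = FALSE])
}

#' Posterior weights of all three components
#'
#' @param fit a \linkS4class{ThreePoissonFit}.
#' @param counts integer vector of window counts.
#' @return numeric matrix, length(counts) x 3, rows summing to 1.
#' @export
componentPosterior <- function(fit, counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    ld <- vapply(seq_len(3L), function(k) {
        if (fit@weights[k] == 0) rep(-Inf, length(counts))
        else dpois(counts, fit@lambda[k], log = TRUE) + log(fit@weights[k])
    }, numeric(length(counts)))
    if (length(counts) == 1L) ld <- matrix(ld, nrow = 1L)
    m <- apply(ld, 1L, max)
    p <- exp(ld - (m + log(rowSums(exp(ld - m)))))
    p
}

#' Binary methylation status from posteriors
#'
#' @param pMeth numeric vector or matrix of methylation posteriors.
#' @param tau posterior threshold in (0, 1); a window is methylated when its
#'   posterior is at or above \code{tau} (default 0.5).
#' @return logical vector or matrix of the same shape.
#' @export
callStatus <- function(pMeth, tau = 0.5) {
    if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
    pMeth >= tau
}

#' Posterior methylation matrix for a WindowCounts object
#'
#' Applies each sample's fit to its full count column.  Windows outside
#' \code{retained} are forced to posterior 0: the filter has already judged
#' them indistinguishable from even-coverage noise, and the scan should not
#' resurrect them.
#'
#' When every retained window of a sample carries methylated signal (e.g.
#' the differential structure is purely quantitative), all three mixture
#' components collapse onto one high rate and the within-mixture posterior
#' is uninformative.  If that collapsed rate reaches the sample's filter
#' threshold, the posterior is instead computed from an equal-weight
#' two-point contrast between the sample's even-coverage background rate
#' and the collapsed rate, so enriched windows are still recognised as
#' methylated while stray background counts are not.  This rescue needs
#' the \code{filter} result; without it the plain mixture posterior is
#' used.
#'
#' @param x a \linkS4class{WindowCounts}.
#' @param fits list of \linkS4class{ThreePoissonFit} from [fitSamples()].
#' @param retained integer indices of filter-retained windows (default all).
#' @param filter optional \linkS4class{PoissonFilterResult} supplying the
#'   per-sample background rates and thresholds for collapsed fits.
#' @param collapseSd collapse criterion in Poisson standard deviations
#'   (default 2), see [methylationProbability()].
#' @return numeric matrix, windows x samples, of methylation posteriors.
#' @export
posteriorMatrix <- function(x, fits, retained = seq_len(nrow(x)),
                            filter = NULL, collapseSd = 2) {
    counts <- assay(x, "counts")
    p <- matrix(0, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
    for (s in seq_len(ncol(counts))) {
        f <- fits[[s]]
        lam <- f@lambda
        allCollapsed <- lam[3L] - lam[1L] <= collapseSd * sqrt(lam[3L])
        cc <- counts[retained, s]
        if (allCollapsed && !is.null(filter) &&
            lam[3L] >= filter@threshold[s]) {
            bg <- max(filter@lambda[s], 1e-6)
            l1 <- dpois(cc, bg, log = TRUE)
            l3 <- dpois(cc, lam[3L], log = TRUE)
            m <- pmax(l1, l3)
            p[retained, s] <- exp(l3 - m) / (exp(l1 - m) + exp(l3 - m))
        } else {
            p[retained, s] <- methylationProbability(f, cc,
                                                     collapseSd = collapseSd)
        }
    }
    p
}

#' Write the per-sample mixture fit report as TSV
#' @param fits named list of \linkS4class{ThreePoissonFit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFitReport <- function(fits, path) {
    if (length(fits) == 0L) {
        df <- data.frame(sample = character(0), lambda1 = numeric(0),
                         lambda2 = numeric(0), lambda3 = numeric(0),
                         pi1 = numeric(0), pi2 = numeric(0),
                         pi3 = numeric(0), iterations = integer(0),
                         converged = logical(0), degenerate = logical(0))
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        return(invisible(path))
    }
    df <- do.call(rbind, lapply(names(fits), function(s) {
        f <- fits[[s]]
        data.frame(sample = s,
                   lambda1 = f@lambda[1], lambda2 = f@lambda[2],
                   lambda3 = f@lambda[3],
                   pi1 = f@weights[1], pi2 = f@weights[2],
                   pi3 = f@weights[3],
                   iterations = f@nIter, converged = f@converged,
                   degenerate = f@degenerate)
    }))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
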