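#' Centered, unscaled PCA of sample density profiles
#'
#' Observations are samples, variables are peaks. Columns are mean-centered
#' and not scaled, so the analysis is an eigenanalysis of the covariance
#' matrix and the eigenvalue sum equals the total variance (inertia) of the
#' centered data. The covariance divisor is \code{nDivisor} per variable
#' (default the number of samples \eqn{n}, the inertia convention of
#' centered-PCA frameworks; set \code{nDivisor = n - 1} for the unbiased
#' convention — eigenvalue ratios are unaffected).
#'
#' Computed by singular value decomposition of the centered matrix; each
#' axis' sign is fixed by forcing its largest-magnitude loading positive, so
#' scores are deterministic across eigensolvers.
#'
#' @param pm a \code{\linkS4class{PeakMatrix}}, or a samples x peaks
#'   numeric matrix
#' @param nDivisor covariance divisor (default: number of samples)
#' @return a \code{PeakPCA} object with slots \code{scores} (samples x
#'   components), \code{loadings} (peaks x components), \code{eigenvalues},
#'   \code{varianceExplained}, \code{totalVariance}
#' @export
genomePca <- function(pm, nDivisor = NULL) {
    X <- if (is(pm, "PeakMatrix")) t(densities(pm)) else as.matrix(pm)
    n <- nrow(X)
    if (n < 2L) stop("at least 2 samples are required")
    if (is.null(nDivisor)) nDivisor <- n
    Xc <- sweep(X, 2L, colMeans(X))
    sv <- svd(Xc)
    ncomp <- min(dim(X))
    eig <- (sv$d^2 / nDivisor)[seq_len(ncomp)]
    scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
        diag(sv$d[seq_len(ncomp)], ncomp)
    loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
    ## deterministic sign: largest-|loading| entry positive per axis
    for (j in seq_len(ncomp)) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    total <- sum(eig)
    ve <- if (total > 0) eig / total else rep(NaN, ncomp)
    dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncomp)))
    dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncomp)))
    new("PeakPCA", scores = scores, loadings = loadings, eigenvalues = eig,
        varianceExplained = ve, totalVariance = total)
}

#' @rdname genomePca
#' @export
setClass("PeakPCA", representation(scores = "matrix", loadings = "matrix",
                                   eigenvalues = "numeric",
                                   varianceExplained = "numeric",
                                   totalVariance = "numeric"))

setValidity("PeakPCA", function(object) {
    msg <- character(0)
    ev <- object@eigenvalues
    if (any(ev < -1e-8 * max(abs(ev), 1)))
        msg <- c(msg, "eigenvalues must be non-negative")
    if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-8 * max(ev, 1)))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PeakPCA", function(object) {
    ncomp <- length(object@eigenvalues)
    cat(sprintf("PeakPCA: %d samples, %d components, total variance %.4g\n",
                nrow(object@scores), ncomp, object@totalVariance))
    ve <- utils::head(object@varianceExplained, 3L)
    cat("variance explained:",
        paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve), collapse = ", "),
        "\n")
})

#' @rdname genomePca
#' @param x a \code{PeakPCA}
#' @export
pcaScores <- function(x) x@scores

#' @rdname genomePca
#' @export
eigenvalues <- function(x) x@eigenvalues

#' @rdname genomePca
#' @export
varianceExplained <- function(x) x@varianceExplained

#' Per-species centroids in principal-component space
#'
#' The center of a species' ellipse of dispersion is the arithmetic mean of
#' its samples' scores in the first \code{nComponents} axes.
#'
#' @param pca a \code{PeakPCA}
#' @param speciesLabels species label per sample (in score row order)
#' @param nComponents number of leading components (default 2)
#' @return matrix, species x components
#' @export
speciesCentroids <- function(pca, speciesLabels, nComponents = 2L) {
    sc <- pcaScores(pca)
    if (nComponents > ncol(sc))
        stop("nComponents exceeds available components")
    g <- factor(speciesLabels)
    if (length(g) != nrow(sc))
        stop("speciesLabels length must match the number of samples")
    sc <- sc[, seq_len(nComponents), drop = FALSE]
    cent <- rowsum(sc, g) / as.integer(table(g))
    cent
}

## pairwise Euclidean distances between centroid rows, as a long DataFrame
.pairwiseDistances <- function(cent) {
    sp <- rownames(cent)
    pairs <- utils::combn(sp, 2L)
    d <- apply(pairs, 2L, function(p)
        sqrt(sum((cent[p[1L], ] - cent[p[2L], ])^2)))
    DataFrame(species_a = pairs[1L, ], species_b = pairs[2L, ], distance = d)
}

#' Sliding windows along chromosomes
#'
#' Windows of \code{windowBp} starting every \code{stepBp} from the
#' chromosome start; the last full window starts at or before
#' \code{length - windowBp}. A chromosome shorter than one window yields a
#' single truncated window covering it entirely.
#'
#' @param chromLengths named vector of chromosome lengths (bp)
#' @param windowBp window size in bp (default 1e6)
#' @param stepBp step size in bp (default 1e5); must not exceed windowBp
#' @return \code{GRanges} of windows, ordered by chromosome then start
#' @examples
#' makeSlidingWindows(c(chr1 = 2000000))  # 11 windows of 1 Mb every 100 kb
#' @export
makeSlidingWindows <- function(chromLengths, windowBp = 1000000L,
                            stepBp = 100000L) {
    if (stepBp < 1 || windowBp < stepBp)
        stop("need windowBp >= stepBp >= 1")
    grl <- lapply(names(chromLengths), function(chrom) {
        len <- chromLengths[[chrom]]
        if (len < windowBp)
            return(GRanges(chrom, IRanges(1L, len),
                           seqlengths = chromLengths))
        starts <- seq(0L, len - windowBp, by = stepBp)
        GRanges(chrom, IRanges(starts + 1L, width = windowBp),
                seqlengths = chromLengths)
    })
    do.call(c, grl)
}

#' Windowed between-species divergence from per-window PCA
#'
#' For each window, restricts the peak matrix to peaks overlapping the
#' window, re-runs the centered unscaled PCA on those peaks, places each
#' species' centroid in the first \code{nComponents} axes, and records all
#' pairwise Euclidean distances between centroids. Windows with fewer than
#' \code{minPeaks} peaks get \code{NA} distances (a near-empty window has no
#' meaningful axes).
#'
#' @param pm a \code{\linkS4class{PeakMatrix}}
#' @param windows \code{GRanges} of windows (see \code{\link{makeSlidingWindows}})
#' @param nComponents components used for centroid distances (default 2)
#' @param minPeaks minimum peaks per window (default 2)
#' @return a \code{DataFrame}, one row per window per species pair:
#'   \code{chrom}, \code{start} (0-based), \code{end}, \code{n_peaks},
#'   \code{mean_density}, \code{species_a}, \code{species_b},
#'   \code{distance}
#' @export
windowedDivergence <- function(pm, windows, nComponents = 2L, minPeaks = 2L) {
    stopifnot(is(pm, "PeakMatrix"))
    g <- factor(species(pm))
    pairs <- utils::combn(levels(g), 2L)
    hits <- findOverlaps(rowRanges(pm), windows, ignore.strand = TRUE)
    byWin <- split(queryHits(hits), factor(subjectHits(hits),
                                           levels = seq_along(windows)))
    rows <- lapply(seq_along(windows), function(w) {
        idx <- byWin[[w]]
        base <- DataFrame(chrom = as.character(seqnames(windows)[w]),
                          start = start(windows)[w] - 1L,
                          end = end(windows)[w],
                          n_peaks = length(idx),
                          mean_density = if (length(idx))
                              mean(densities(pm)[idx, , drop = FALSE]) else NA_real_)
        if (length(idx) < minPeaks) {
            dd <- DataFrame(species_a = pairs[1L, ], species_b = pairs[2L, ],
                            distance = NA_real_)
        } else {
            pca <- genomePca(t(densities(pm)[idx, , drop = FALSE]))
            nc <- min(nComponents, ncol(pcaScores(pca)))
            cent <- speciesCentroids(pca, g, nComponents = nc)
            dd <- .pairwiseDistances(cent)
        }
        cbind(base[rep(1L, nrow(dd)), , drop = FALSE], dd)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
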