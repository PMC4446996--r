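#' Spearman rank correlation with a large-sample p-value
#'
#' Average-rank ties; p-value from the standard large-sample (t)
#' approximation (\code{stats::cor.test}, \code{exact = FALSE}). Pairs with
#' a missing value in either vector are dropped first. A constant vector
#' leaves rho undefined (\code{NA}, \code{defined = FALSE}).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs)
#' @param labels length-2 character vector naming the variable pair
#' @return a \code{DataFrame} (one row): \code{var_x}, \code{var_y},
#'   \code{n}, \code{spearman_rho}, \code{p_value}, \code{defined}
#' @export
spearmanCor <- function(x, y, labels = c("x", "y")) {
    if (length(x) != length(y)) stop("x and y differ in length")
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3L) stop("need at least 3 complete pairs")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        return(DataFrame(var_x = labels[1L], var_y = labels[2L], n = n,
                         spearman_rho = NA_real_, p_value = NA_real_,
                         defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    DataFrame(var_x = labels[1L], var_y = labels[2L], n = n,
              spearman_rho = unname(ct$estimate), p_value = ct$p.value,
              defined = TRUE)
}

#' Spearman correlation of within- vs between-species sums of squares
#'
#' The per-peak \code{ss_within} and \code{ss_between} of an ANEVA table are
#' not independent in real data; this reports their rank correlation.
#'
#' @param anevaTab result of \code{\link{anevaTable}} (>= 3 peaks)
#' @return one-row \code{DataFrame} as \code{\link{spearmanCor}}
#' @export
ssCorrelation <- function(anevaTab) {
    spearmanCor(anevaTab$ss_within, anevaTab$ss_between,
                labels = c("ss_within", "ss_between"))
}

#' Join windows with SNP counts and peak summaries
#'
#' Attributes the counts of an interval track (e.g. SNPs per interval) to
#' sliding windows proportionally to the overlap fraction of each interval:
#' sliding windows overlap each other, so point-assignment would double
#' count ambiguously, while proportional attribution is deterministic and
#' additive. The output pairs each window's \code{snp_count} with its
#' \code{n_peaks} and \code{mean_density} (from
#' \code{\link{windowedDivergence}} rows, or computed here when a
#' \code{PeakMatrix} is given), ready for \code{\link{spearmanCor}}.
#'
#' @param windows \code{GRanges} of windows
#' @param snpTrack count \code{GRanges} from \code{\link{readBed}(type =
#'   "counts")}; may be empty (all counts 0)
#' @param pm optional \code{PeakMatrix} used to compute per-window
#'   \code{n_peaks} and \code{mean_density}
#' @return a \code{DataFrame}, one row per window: \code{chrom},
#'   \code{start} (0-based), \code{end}, \code{snp_count}, and with
#'   \code{pm} also \code{n_peaks}, \code{mean_density}
#' @export
windowCovariateTable <- function(windows, snpTrack, pm = NULL) {
    snp <- numeric(length(windows))
    if (length(snpTrack)) {
        hits <- findOverlaps(windows, snpTrack, ignore.strand = TRUE)
        if (length(hits)) {
            ov <- width(pintersect(windows[queryHits(hits)],
                                   snpTrack[subjectHits(hits)]))
            frac <- ov / width(snpTrack)[subjectHits(hits)]
            contrib <- snpTrack$count[subjectHits(hits)] * frac
            agg <- rowsum(contrib, queryHits(hits))
            snp[as.integer(rownames(agg))] <- agg[, 1L]
        }
    }
    out <- DataFrame(chrom = as.character(seqnames(windows)),
                     start = start(windows) - 1L, end = end(windows),
                     snp_count = snp)
    if (!is.null(pm)) {
        hits <- findOverlaps(rowRanges(pm), windows, ignore.strand = TRUE)
        out$n_peaks <- as.integer(countOverlaps(windows, rowRanges(pm),
                                                ignore.strand = TRUE))
        md <- rep(NA_real_, length(windows))
        if (length(hits)) {
            pmMean <- rowMeans(densities(pm))
            agg <- rowsum(pmMean[queryHits(hits)], subjectHits(hits))
            md[as.integer(rownames(agg))] <-
                agg[, 1L] / out$n_peaks[as.integer(rownames(agg))]
        }
        out$mean_density <- md
    }
    out
}

#' Over-representation of a gene set among top-ranked genes
#'
#' Ranks genes by score (descending; ties broken by larger \code{n_peaks},
#' then lexicographic gene id), takes the top \code{k}, and tests
#' over-representation of the \code{deGenes} set by the upper-tail
#' hypergeometric probability \eqn{P(X \ge m)} with
#' \eqn{X \sim } Hypergeom(\eqn{N, K, k}): \eqn{N} universe size, \eqn{K}
#' set members in the universe, \eqn{m} the observed overlap. With
#' \code{method = "permutation"}, \eqn{p} is instead estimated by drawing
#' random size-\eqn{K} label sets (+1-corrected tail proportion).
#'
#' The universe is the intersection of genes with a defined score and the
#' supplied \code{universe} (when given), mirroring the overlap-restricted
#' universe of cross-dataset comparisons.
#'
#' @param scores a \code{DataFrame}/data.frame with \code{gene_id}, a score
#'   column and optionally \code{n_peaks}
#' @param deGenes character vector of gene ids in the set of interest
#' @param k number of top-ranked genes to take
#' @param universe optional character vector restricting the gene universe
#' @param scoreCol name of the score column (default \code{"mean_epi_fst"})
#' @param method \code{"hypergeometric"} (default) or \code{"permutation"}
#' @param nPerm,seed permutation-mode controls
#' @return a \code{DataFrame} (one row): \code{universe_size},
#'   \code{de_in_universe}, \code{top_size}, \code{overlap}, \code{p_value},
#'   \code{method}
#' @export
topKEnrichment <- function(scores, deGenes, k, universe = NULL,
                           scoreCol = "mean_epi_fst",
                           method = c("hypergeometric", "permutation"),
                           nPerm = 10000L, seed = NULL) {
    method <- match.arg(method)
    if (k <= 0) stop("k must be positive")
    df <- as.data.frame(scores)
    if (!scoreCol %in% colnames(df)) stop("no score column '", scoreCol, "'")
    df <- df[!is.na(df[[scoreCol]]), , drop = FALSE]
    if (!is.null(universe)) df <- df[df$gene_id %in% universe, , drop = FALSE]
    N <- nrow(df)
    if (N == 0L) stop("empty universe")
    if (k > N) stop("k exceeds the universe size (", N, ")")
    npk <- if ("n_peaks" %in% colnames(df)) df$n_peaks else rep(0L, N)
    o <- order(-df[[scoreCol]], -npk, df$gene_id)
    top <- df$gene_id[o][seq_len(k)]
    deU <- intersect(unique(deGenes), df$gene_id)
    K <- length(deU)
    m <- length(intersect(top, deU))
    p <- if (method == "hypergeometric") {
        stats::phyper(m - 1, K, N - K, k, lower.tail = FALSE)
    } else {
        if (!is.null(seed)) set.seed(seed)
        r <- sum(vapply(seq_len(nPerm), function(i)
            length(intersect(top, sample(df$gene_id, K))) >= m, logical(1L)))
        (r + 1) / (nPerm + 1)
    }
    DataFrame(universe_size = N, de_in_universe = K, top_size = as.integer(k),
              overlap = as.integer(m), p_value = p, method = method)
}
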