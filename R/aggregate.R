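## per-species within sums of squares and variances for each row of Y
## (decomposes SS_within: sum over species of SS_s equals SS_within exactly)
.withinSpeciesStats <- function(Y, g, requireReplicates = TRUE) {
    g <- factor(g)
    ni <- as.integer(table(g))
    if (requireReplicates && any(ni < 2L))
        stop("species with fewer than 2 samples: ",
             paste(levels(g)[ni < 2L], collapse = ", "))
    ss <- matrix(0, nrow(Y), nlevels(g), dimnames = list(rownames(Y), levels(g)))
    va <- ss
    for (j in seq_len(nlevels(g))) {
        Ys <- Y[, g == levels(g)[j], drop = FALSE]
        m <- rowSums(Ys) / ni[j]
        ss[, j] <- pmax(rowSums(Ys * Ys) - ni[j] * m^2, 0)
        va[, j] <- ss[, j] / (ni[j] - 1L)
    }
    list(ss = ss, var = va)
}

#' Within-species sums of squares and variances for one peak
#'
#' Decomposes the within-species sum of squares by species:
#' \eqn{SS_s = \sum_j (y_{sj} - \bar y_{s\cdot})^2} with variance
#' \eqn{SS_s/(n_s - 1)}. Over all species the \eqn{SS_s} sum exactly to the
#' \code{ss_within} of \code{\link{varianceComponents}}.
#'
#' @inheritParams varianceComponents
#' @return a \code{DataFrame} with one row per species: \code{species},
#'   \code{n}, \code{ss_within}, \code{variance}
#' @examples
#' withinSpeciesVariance(c(0, 2, 4, 1, 1), c("h","h","h","c","c"))
#' @export
withinSpeciesVariance <- function(values, speciesLabels) {
    st <- .withinSpeciesStats(matrix(as.numeric(values), nrow = 1L),
                              speciesLabels)
    g <- factor(speciesLabels)
    DataFrame(species = levels(g), n = as.integer(table(g)),
              ss_within = unname(st$ss[1L, ]), variance = unname(st$var[1L, ]))
}

## extend gene intervals by flankBp on both sides, clamped at position 1
## and (when seqlengths are known) at the chromosome end
.extendGenes <- function(genes, flankBp) {
    ext <- genes
    newEnd <- end(genes) + flankBp
    sl <- seqlengths(genes)[as.character(seqnames(genes))]
    newEnd <- ifelse(is.na(sl), newEnd, pmin(newEnd, sl))
    ranges(ext) <- IRanges(pmax(start(genes) - flankBp, 1L), newEnd)
    ext
}

#' Assign peaks to genes within a flanked gene interval
#'
#' A peak belongs to a gene when it lies within the gene body extended by
#' \code{flankBp} on both sides (strand-ignorant: both ends are extended
#' equally). \code{mode = "overlap"} (default) requires any overlap of the
#' peak interval with the extended interval; \code{mode = "midpoint"}
#' requires the peak midpoint to fall inside it. A peak may be assigned to
#' several genes.
#'
#' @param pm a \code{PeakMatrix} (or a \code{GRanges} of peaks with names)
#' @param genes a gene \code{GRanges} with a \code{gene_id} column (from
#'   \code{\link{readBed}(type = "genes")})
#' @param flankBp flank in bp added to both gene ends (default 50000)
#' @param mode \code{"overlap"} or \code{"midpoint"}
#' @return a \code{DataFrame} with columns \code{gene_id}, \code{peak_id}
#' @export
assignPeaksToGenes <- function(pm, genes, flankBp = 50000L,
                               mode = c("overlap", "midpoint")) {
    mode <- match.arg(mode)
    if (flankBp < 0) stop("flankBp must be >= 0")
    peaks <- if (is(pm, "PeakMatrix")) rowRanges(pm) else pm
    if (is.null(names(peaks))) stop("peaks must carry peak ids as names")
    ext <- .extendGenes(genes, as.integer(flankBp))
    query <- if (mode == "midpoint") {
        mid <- (start(peaks) + end(peaks)) %/% 2L
        GRanges(seqnames(peaks), IRanges(mid, width = 1L))
    } else peaks
    hits <- findOverlaps(query, ext, ignore.strand = TRUE)
    DataFrame(gene_id = genes$gene_id[subjectHits(hits)],
              peak_id = names(peaks)[queryHits(hits)])
}

#' Per-gene averages of per-peak statistics
#'
#' Averages the per-peak epi-FST (and the per-species within variances) over
#' all peaks assigned to each gene, giving one epigenetic FST per gene.
#' Peaks whose statistic is undefined are dropped from the mean and flagged
#' via \code{n_defined < n_peaks} (treating them as 0 would bias the mean
#' toward no differentiation). Genes with no contributing peak are emitted
#' with \code{NA} scores and \code{n_peaks = 0}.
#'
#' @param anevaTab result of \code{\link{anevaTable}}
#' @param assignment gene/peak assignment from
#'   \code{\link{assignPeaksToGenes}}
#' @param genes gene \code{GRanges}; every \code{gene_id} appears in the
#'   output even when no peak maps to it
#' @return a \code{DataFrame} with \code{gene_id}, \code{n_peaks},
#'   \code{n_defined}, \code{mean_epi_fst}, \code{partial} (TRUE when some
#'   assigned peaks were undefined), and \code{mean_var_within_<species>}
#' @export
geneScores <- function(anevaTab, assignment, genes) {
    idx <- match(assignment$peak_id, anevaTab$peak_id)
    if (anyNA(idx))
        stop("assignment refers to peaks absent from the ANEVA table: ",
             assignment$peak_id[which(is.na(idx))[1L]])
    geneIds <- genes$gene_id
    gfac <- factor(assignment$gene_id, levels = geneIds)
    fst <- anevaTab$epi_fst[idx]
    nPeaks <- as.integer(table(gfac))
    ok <- !is.na(fst)
    nDef <- integer(length(geneIds))
    sums <- numeric(length(geneIds))
    agg <- rowsum(cbind(def = as.numeric(ok),
                        fst = ifelse(ok, fst, 0)), gfac)
    pos <- match(rownames(agg), geneIds)
    nDef[pos] <- as.integer(agg[, "def"])
    sums[pos] <- agg[, "fst"]
    meanFst <- ifelse(nDef > 0, sums / nDef, NA_real_)
    out <- DataFrame(gene_id = geneIds, n_peaks = nPeaks, n_defined = nDef,
                     mean_epi_fst = meanFst,
                     partial = nDef < nPeaks & nPeaks > 0L)
    varCols <- grep("^var_within_", colnames(anevaTab), value = TRUE)
    for (vc in varCols) {
        v <- anevaTab[[vc]][idx]
        vok <- !is.na(v)
        aggv <- rowsum(cbind(n = as.numeric(vok), s = ifelse(vok, v, 0)), gfac)
        nv <- numeric(length(geneIds)); sv <- numeric(length(geneIds))
        posv <- match(rownames(aggv), geneIds)
        nv[posv] <- aggv[, "n"]; sv[posv] <- aggv[, "s"]
        out[[paste0("mean_", vc)]] <- ifelse(nv > 0, sv / nv, NA_real_)
    }
    out
}

#' Fraction of peaks near transcription start sites
#'
#' Classifies each peak by whether it overlaps a +/- \code{windowBp} window
#' around any TSS. With \code{tssMode = "unique"} a single TSS per gene is
#' used — the one belonging to the longest transcript (\code{tx_length}
#' column of the TSS track), ties broken by the smallest coordinate; with
#' \code{"all"} every known TSS is an anchor. Each peak is counted at most
#' once. \code{windowBp = 0} degenerates to overlap with the exact TSS
#' position.
#'
#' @param pm a \code{PeakMatrix} (or peak \code{GRanges})
#' @param tss TSS \code{GRanges} from \code{\link{readBed}(type = "tss")}
#' @param windowBp half-width of the TSS window in bp (default 2000)
#' @param tssMode \code{"unique"} or \code{"all"}
#' @return a \code{DataFrame} (one row) with \code{window_bp},
#'   \code{tss_mode}, \code{n_peaks_total}, \code{n_peaks_near_tss},
#'   \code{fraction_near_tss}
#' @export
tssProximity <- function(pm, tss, windowBp = 2000L,
                         tssMode = c("unique", "all")) {
    tssMode <- match.arg(tssMode)
    if (windowBp < 0) stop("windowBp must be >= 0")
    peaks <- if (is(pm, "PeakMatrix")) rowRanges(pm) else pm
    if (length(peaks) == 0L) stop("empty peak set")
    if (tssMode == "unique") {
        if (is.null(tss$gene_id)) stop("TSS track lacks gene_id")
        len <- tss$tx_length
        if (all(is.na(len))) len <- rep(0, length(tss))
        o <- order(tss$gene_id, -ifelse(is.na(len), -Inf, len), start(tss))
        tss <- tss[o][!duplicated(tss$gene_id[o])]
    }
    win <- GRanges(seqnames(tss),
                   IRanges(pmax(start(tss) - windowBp, 1L),
                           end(tss) + windowBp))
    near <- overlapsAny(peaks, win, ignore.strand = TRUE)
    DataFrame(window_bp = as.integer(windowBp), tss_mode = tssMode,
              n_peaks_total = length(peaks),
              n_peaks_near_tss = sum(near),
              fraction_near_tss = mean(near))
}
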