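#' Parameters for the peak-density simulator
#'
#' Houses the quantities of the one-way random-effects model: the grand
#' mean density \code{mu}, the between-species variance \code{sigma2Alpha}
#' of the species effects, the within-species variance \code{sigma2Eps} of
#' the individual effects, and the design (per-species sample sizes, number
#' of peaks, genome). Defaults state the simulated world once: sample sizes
#' \{human 11, chimp 4, macaque 3\} matching the real three-species design's
#' unbalancedness, \code{mu = 10} with unit variances so that truncation of
#' negative densities at 0 is negligible, 1-kb peaks on a 2 x 50-Mb toy
#' genome.
#'
#' @param mu grand mean density (default 10)
#' @param sigma2Alpha between-species variance component (default 1)
#' @param sigma2Eps within-species variance component (default 1)
#' @param speciesSizes named vector of samples per species (each >= 2)
#' @param nPeaks number of peaks (default 1000)
#' @param fractionDivergent fraction of peaks simulated with
#'   \code{sigma2Alpha > 0}; the rest have no species effect (default 1)
#' @param chromLengths named vector of chromosome lengths
#' @param peakWidth peak width in bp (default 1000)
#' @param placement \code{"regular"} (evenly spaced) or \code{"random"}
#'   (uniform non-overlapping)
#' @param seed integer seed; every draw is governed by it
#' @return a validated \code{SimulationParams} list
#' @export
simulationParams <- function(mu = 10, sigma2Alpha = 1, sigma2Eps = 1,
                             speciesSizes = c(human = 11L, chimp = 4L,
                                              macaque = 3L),
                             nPeaks = 1000L, fractionDivergent = 1,
                             chromLengths = c(chr1 = 5e7, chr2 = 5e7),
                             peakWidth = 1000L,
                             placement = c("regular", "random"),
                             seed = 1L) {
    placement <- match.arg(placement)
    if (sigma2Alpha < 0 || sigma2Eps < 0) stop("variances must be >= 0")
    if (any(speciesSizes < 2L))
        stop("every species needs >= 2 samples")
    if (is.null(names(speciesSizes))) stop("speciesSizes must be named")
    if (fractionDivergent < 0 || fractionDivergent > 1)
        stop("fractionDivergent must be in [0, 1]")
    if (nPeaks < 1L) stop("nPeaks must be >= 1")
    structure(list(mu = mu, sigma2Alpha = sigma2Alpha,
                   sigma2Eps = sigma2Eps, speciesSizes = speciesSizes,
                   nPeaks = as.integer(nPeaks),
                   fractionDivergent = fractionDivergent,
                   chromLengths = chromLengths,
                   peakWidth = as.integer(peakWidth),
                   placement = placement, seed = as.integer(seed)),
              class = "SimulationParams")
}

## non-overlapping peak placement on a slot grid of peakWidth
.placePeaks <- function(params) {
    w <- params$peakWidth
    slots <- floor(params$chromLengths / w)
    if (params$nPeaks > sum(slots))
        stop("cannot place ", params$nPeaks, " non-overlapping peaks of ",
             w, " bp on a genome with ", sum(slots), " slots")
    chroms <- rep(names(params$chromLengths), slots)
    slotIdx <- unlist(lapply(slots, seq_len), use.names = FALSE)
    pick <- if (params$placement == "regular") {
        round(seq(1L, sum(slots), length.out = params$nPeaks))
    } else {
        sort(sample.int(sum(slots), params$nPeaks))
    }
    start0 <- (slotIdx[pick] - 1L) * w
    GRanges(chroms[pick], IRanges(start0 + 1L, width = w))
}

#' Simulate a peak density matrix with known variance components
#'
#' For each peak, species effects are drawn as
#' \eqn{\alpha_i \sim N(0, \sigma^2_\alpha)} (identically zero for
#' non-divergent peaks) and individual effects as
#' \eqn{\epsilon_{ij} \sim N(0, \sigma^2_\epsilon)}; the density is
#' \eqn{Y_{ij} = \mu + \alpha_i + \epsilon_{ij}}, truncated at 0. Normal
#' draws make the ANOVA expectations exact, so the natural estimators can be
#' checked for unbiasedness against the generating values. If truncation
#' affects more than 1\% of draws a warning is raised (the variance
#' structure is then distorted) and the fraction is recorded.
#'
#' The per-peak generating values are stored in \code{rowData}:
#' \code{true_sigma2_alpha}, \code{true_sigma2_eps}, \code{divergent}.
#'
#' @param params a \code{\link{simulationParams}} object
#' @return a \code{\linkS4class{PeakMatrix}}; \code{metadata} carries the
#'   parameters and the clamped fraction
#' @export
simulatePeakMatrix <- function(params) {
    stopifnot(inherits(params, "SimulationParams"))
    set.seed(params$seed)
    gr <- .placePeaks(params)
    k <- length(params$speciesSizes)
    N <- sum(params$speciesSizes)
    sp <- rep(names(params$speciesSizes), params$speciesSizes)
    nP <- params$nPeaks
    nDiv <- round(params$fractionDivergent * nP)
    divergent <- logical(nP)
    divergent[sample.int(nP, nDiv)] <- TRUE
    alpha <- matrix(stats::rnorm(nP * k, 0, sqrt(params$sigma2Alpha)), nP, k)
    alpha[!divergent, ] <- 0
    eps <- matrix(stats::rnorm(nP * N, 0, sqrt(params$sigma2Eps)), nP, N)
    spIdx <- rep(seq_len(k), params$speciesSizes)
    Y <- params$mu + alpha[, spIdx, drop = FALSE] + eps
    clamped <- mean(Y < 0)
    if (clamped > 0.01)
        warning(sprintf("truncation at 0 affected %.1f%% of draws; %s",
                        100 * clamped,
                        "variance components are distorted"))
    Y[Y < 0] <- 0
    dimnames(Y) <- list(sprintf("peak_%05d", seq_len(nP)),
                        make.unique(paste0(sp, "_", sequence(params$speciesSizes))))
    pm <- PeakMatrix(Y, gr, species = sp)
    rowData(pm)$true_sigma2_alpha <-
        ifelse(divergent, params$sigma2Alpha, 0)
    rowData(pm)$true_sigma2_eps <- params$sigma2Eps
    rowData(pm)$divergent <- divergent
    metadata(pm) <- list(params = params, clamped_fraction = clamped)
    pm
}

#' Simulate gene, TSS, SNP and differential-expression annotation
#'
#' Genes tile the genome at regular spacing; each gene gets one primary TSS
#' at its 5' end (the longest transcript) plus 0-2 alternative TSSs inside
#' the body with shorter transcript lengths, so both TSS-selection modes are
#' exercised. A SNP track of non-overlapping bins carries Poisson counts.
#' Differentially-expressed genes are drawn with sampling weight
#' \code{divergentGeneBias} for genes having a divergent peak within
#' \code{flankBp} (weight 1 otherwise); \code{divergentGeneBias = 1} means
#' no association between divergence and expression.
#'
#' @param pm a simulated \code{PeakMatrix} (its \code{rowData$divergent}
#'   drives the DE bias); optional when \code{divergentGeneBias = 1}
#' @param chromLengths named chromosome lengths (default: from \code{pm})
#' @param nGenes number of genes (default 200)
#' @param geneWidth gene length in bp (default 10000)
#' @param deFraction fraction of genes labeled differentially expressed
#' @param divergentGeneBias sampling weight multiplier for genes near
#'   divergent peaks (default 1 = null)
#' @param flankBp flank defining "near" (default 50000)
#' @param snpBinBp SNP track bin width (default 10000)
#' @param snpRate expected SNPs per bin (default 5)
#' @param seed integer seed
#' @return a list: \code{genes} (GRanges with \code{gene_id}), \code{tss}
#'   (GRanges with \code{gene_id}, \code{tx_length}), \code{deGenes}
#'   (character), \code{snps} (count GRanges)
#' @export
simulateAnnotation <- function(pm = NULL, chromLengths = NULL, nGenes = 200L,
                               geneWidth = 10000L, deFraction = 0.1,
                               divergentGeneBias = 1, flankBp = 50000L,
                               snpBinBp = 10000L, snpRate = 5, seed = 1L) {
    if (nGenes < 1L) stop("nGenes must be >= 1")
    if (is.null(chromLengths)) {
        if (is.null(pm)) stop("need pm or chromLengths")
        p <- metadata(pm)$params
        chromLengths <- p$chromLengths
    }
    set.seed(seed)
    perChrom <- pmax(1L, round(nGenes * chromLengths / sum(chromLengths)))
    gchrom <- rep(names(chromLengths), perChrom)
    gstart <- unlist(lapply(seq_along(chromLengths), function(ci)
        round(seq(1, chromLengths[ci] - geneWidth,
                  length.out = perChrom[ci]))), use.names = FALSE)
    genes <- GRanges(gchrom, IRanges(gstart, width = geneWidth),
                     strand = sample(c("+", "-"), length(gchrom),
                                     replace = TRUE),
                     seqlengths = chromLengths)
    genes <- genes[seq_len(min(nGenes, length(genes)))]
    genes$gene_id <- sprintf("gene_%04d", seq_along(genes))
    ## primary TSS at the 5' end (longest transcript = full gene width),
    ## alternatives inside the body with shorter transcripts
    nAlt <- sample(0:2, length(genes), replace = TRUE)
    fivePrime <- ifelse(as.character(strand(genes)) == "-",
                        end(genes), start(genes))
    altIdx <- rep(seq_along(genes), nAlt)
    altPos <- start(genes)[altIdx] +
        sample.int(geneWidth - 1L, length(altIdx), replace = TRUE)
    tss <- GRanges(c(as.character(seqnames(genes)),
                     as.character(seqnames(genes))[altIdx]),
                   IRanges(c(fivePrime, altPos), width = 1L),
                   gene_id = c(genes$gene_id, genes$gene_id[altIdx]),
                   tx_length = c(rep(geneWidth, length(genes)),
                                 sample.int(geneWidth - 1L, length(altIdx),
                                            replace = TRUE)),
                   seqlengths = chromLengths)
    ## SNP track: non-overlapping bins with Poisson counts
    nb <- floor(chromLengths / snpBinBp)
    snps <- GRanges(rep(names(chromLengths), nb),
                    IRanges(start = unlist(lapply(nb, function(x)
                        (seq_len(x) - 1L) * snpBinBp + 1L),
                        use.names = FALSE), width = snpBinBp),
                    count = stats::rpois(sum(nb), snpRate),
                    seqlengths = chromLengths)
    ## DE genes, biased toward genes near divergent peaks
    nDe <- round(deFraction * length(genes))
    deGenes <- character(0)
    if (nDe > 0) {
        wt <- rep(1, length(genes))
        if (divergentGeneBias != 1) {
            if (is.null(pm) || is.null(rowData(pm)$divergent))
                stop("divergentGeneBias != 1 needs a simulated PeakMatrix")
            divPeaks <- rowRanges(pm)[rowData(pm)$divergent]
            nearDiv <- overlapsAny(.extendGenes(genes, flankBp), divPeaks,
                                   ignore.strand = TRUE)
            wt[nearDiv] <- divergentGeneBias
        }
        deGenes <- sample(genes$gene_id, nDe, prob = wt)
    }
    list(genes = genes, tss = tss, deGenes = deGenes, snps = snps)
}
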