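test_that("within-species SS and variances match hand algebra and sum", {
    w <- withinSpeciesVariance(c(0, 2, 4, 1, 1), rep(c("h", "c"), c(3, 2)))
    h <- as.data.frame(w)
    expect_equal(h$ss_within[h$species == "h"], 8)
    expect_equal(h$variance[h$species == "h"], 4)
    expect_equal(h$ss_within[h$species == "c"], 0)
    expect_equal(h$variance[h$species == "c"], 0)

    expect_error(withinSpeciesVariance(1:3, c("h", "h", "c")), "fewer than 2")

    set.seed(13)
    for (rep_ in 1:100) {
        ni <- sample(2:9, 2L, replace = TRUE)
        g <- rep(c("h", "c"), ni)
        y <- rnorm(sum(ni), 10)
        vc <- varianceComponents(y, g)
        w <- withinSpeciesVariance(y, g)
        expect_equal(sum(w$ss_within), vc$ss_within, tolerance = 1e-9)
        # per-species variance equals the sample variance
        expect_equal(w$variance[w$species == "h"], var(y[g == "h"]),
                     tolerance = 1e-9)
    }
})

test_that("peak-to-gene assignment uses any-overlap of the flanked gene", {
    # gene [100000,110000) 0-based with 50 kb flanks -> [50000,160000)
    genes <- GRanges("chr1", IRanges(100001, 110000))
    genes$gene_id <- "g1"
    peaks <- GRanges("chr1", IRanges(start = c(49001, 160001, 105001) ,
                                     end = c(50100, 161000, 105500)))
    names(peaks) <- c("boundary_in", "boundary_out", "inside")
    asn <- assignPeaksToGenes(peaks, genes, flankBp = 50000L)
    expect_setequal(asn$peak_id, c("boundary_in", "inside"))

    # flank 0: only the peak strictly inside the gene body
    asn0 <- assignPeaksToGenes(peaks, genes, flankBp = 0L)
    expect_identical(asn0$peak_id, "inside")

    # midpoint mode: the boundary peak's midpoint (49550 0-based) is
    # outside the extended interval start 50000
    asnM <- assignPeaksToGenes(peaks, genes, flankBp = 50000L,
                               mode = "midpoint")
    expect_identical(asnM$peak_id, "inside")

    # a peak may belong to several genes
    genes2 <- c(genes, GRanges("chr1", IRanges(100001, 120000),
                               gene_id = "g2"))
    asn2 <- assignPeaksToGenes(peaks, genes2, flankBp = 50000L)
    expect_identical(sum(asn2$peak_id == "inside"), 2L)
})

test_that("increasing the flank never loses peaks (monotonicity)", {
    pm <- simulatePeakMatrix(simulationParams(nPeaks = 200L, seed = 19L))
    ann <- simulateAnnotation(pm, nGenes = 50L, seed = 20L)
    counts <- vapply(c(0L, 10000L, 50000L, 200000L), function(fl) {
        asn <- assignPeaksToGenes(pm, ann$genes, flankBp = fl)
        nrow(asn)
    }, integer(1L))
    expect_true(all(diff(counts) >= 0))
})

test_that("gene scores average defined peaks and flag partial coverage", {
    genes <- GRanges("chr1", IRanges(c(1, 5001, 9001), width = 1000),
                     gene_id = c("gA", "gB", "gC"))
    tab <- DataFrame(peak_id = c("p1", "p2", "p3"),
                     epi_fst = c(0.2, 0.4, NA_real_),
                     var_within_h = c(1, 3, 2))
    asn <- DataFrame(gene_id = c("gA", "gA", "gB", "gB"),
                     peak_id = c("p1", "p2", "p1", "p3"))
    gs <- geneScores(tab, asn, genes)
    df <- as.data.frame(gs)
    expect_equal(df$mean_epi_fst[df$gene_id == "gA"], 0.3)
    expect_false(df$partial[df$gene_id == "gA"])
    # undefined peak dropped from the mean, flagged
    expect_equal(df$mean_epi_fst[df$gene_id == "gB"], 0.2)
    expect_true(df$partial[df$gene_id == "gB"])
    # gene with no peaks: NA score, zero count
    expect_identical(df$n_peaks[df$gene_id == "gC"], 0L)
    expect_true(is.na(df$mean_epi_fst[df$gene_id == "gC"]))
    # per-species variance averaged over peaks with a value
    expect_equal(df$mean_var_within_h[df$gene_id == "gA"], 2)

    # permutation invariance in peak order; mean bounded by contributors
    asnShuf <- asn[c(3, 1, 4, 2), ]
    expect_equal(as.data.frame(geneScores(tab, asnShuf, genes))$mean_epi_fst,
                 df$mean_epi_fst)
    expect_true(df$mean_epi_fst[1] >= 0.2 && df$mean_epi_fst[1] <= 0.4)
})

test_that("TSS proximity counts peaks once within the +/- window", {
    # peak [1000,1200) 0-based, TSS at 3000, window 2000 -> near
    peaks <- GRanges("chr1", IRanges(start = c(1001, 6001, 9001, 3001),
                                     width = c(200, 100, 100, 10)))
    names(peaks) <- paste0("p", 1:4)
    tss <- GRanges("chr1", IRanges(3001, 3001),
                   gene_id = "g1", tx_length = 500)
    rep_ <- tssProximity(peaks, tss, windowBp = 2000L, tssMode = "all")
    expect_identical(rep_$n_peaks_near_tss, 2L)  # p1 and p4
    expect_equal(rep_$fraction_near_tss, 0.5)

    # degenerate window: only overlap of the exact TSS base counts
    rep0 <- tssProximity(peaks, tss, windowBp = 0L, tssMode = "all")
    expect_identical(rep0$n_peaks_near_tss, 1L)  # p4 covers base 3001

    expect_error(tssProximity(peaks[0], tss), "empty peak set")
})

test_that("unique-TSS mode picks the longest transcript per gene", {
    peaks <- GRanges("chr1", IRanges(c(1001, 50001), width = 100))
    names(peaks) <- c("p1", "p2")
    # gene g1: two TSSs; the longer transcript starts at 50001 (near p2)
    tss <- GRanges("chr1", IRanges(c(1001, 50001), width = 1),
                   gene_id = c("g1", "g1"), tx_length = c(100, 900))
    uni <- tssProximity(peaks, tss, windowBp = 100L, tssMode = "unique")
    all_ <- tssProximity(peaks, tss, windowBp = 100L, tssMode = "all")
    expect_identical(uni$n_peaks_near_tss, 1L)
    expect_identical(all_$n_peaks_near_tss, 2L)
    # all-TSS anchors are a superset: fraction can only grow
    expect_gte(all_$fraction_near_tss, uni$fraction_near_tss)

    # tie on transcript length -> smallest coordinate wins
    tss2 <- GRanges("chr1", IRanges(c(50001, 1001), width = 1),
                    gene_id = c("g1", "g1"), tx_length = c(900, 900))
    uniT <- tssProximity(peaks, tss2, windowBp = 100L, tssMode = "unique")
    expect_identical(uniT$n_peaks_near_tss, 1L)
    expect_identical(
        as.data.frame(tssProximity(peaks[1], tss2, 100L, "unique"))$n_peaks_near_tss,
        1L)
})
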