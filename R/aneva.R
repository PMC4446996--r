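## Vectorized one-way random-effects decomposition over the rows of a
## peaks x samples matrix. Returns per-peak sums of squares, mean squares,
## the effective sample size n0 and the natural variance-component
## estimates S^2 (within, sigma^2_eps) and S^2_alpha (between, sigma^2_alpha).
##
## Model per peak: Y_ij = mu + alpha_i + eps_ij, species effect alpha_i with
## variance sigma^2_alpha, individual effect eps_ij with variance
## sigma^2_eps. SS_between = sum_i n_i (ybar_i - ybar)^2,
## SS_within = sum_i sum_j (y_ij - ybar_i)^2, S^2 = SS_within / (N - k),
## n0 = (N - sum(n_i^2)/N) / (k - 1), S^2_alpha = (MS_between - S^2)/n0.
.anevaStats <- function(Y, g, n0 = NULL) {
    g <- factor(g)
    k <- nlevels(g)
    ni <- as.integer(table(g))
    N <- length(g)
    if (k < 2L) stop("at least 2 species are required")
    if (any(ni < 2L))
        stop("species with fewer than 2 samples: ",
             paste(levels(g)[ni < 2L], collapse = ", "))
    ind <- stats::model.matrix(~ 0 + g)          # samples x k indicator
    gs <- Y %*% ind                              # group sums
    gm <- sweep(gs, 2L, ni, "/")                 # group means ybar_i
    grand <- rowSums(Y) / N
    sumsq <- rowSums(Y * Y)
    ssb <- as.vector((gm - grand)^2 %*% ni)
    ssw <- sumsq - as.vector(gm^2 %*% ni)
    ssw <- pmax(ssw, 0)                          # guard fp negatives
    dfb <- k - 1L
    dfw <- N - k
    msb <- ssb / dfb
    s2 <- ssw / dfw
    n0eff <- if (is.null(n0)) (N - sum(ni^2) / N) / (k - 1L) else n0
    s2a <- (msb - s2) / n0eff
    denom <- s2a + s2
    fst <- ifelse(denom == 0, NA_real_, s2a / denom)
    colnames(gm) <- levels(g)
    list(ss_between = unname(ssb), ss_within = unname(ssw),
         df_between = dfb, df_within = dfw,
         ms_between = unname(msb), s2 = unname(s2), n0 = n0eff,
         s2_alpha = unname(s2a), epi_fst = unname(fst),
         group_means = gm, grand_mean = unname(grand),
         n_i = stats::setNames(ni, levels(g)))
}

#' Per-peak variance components of the analysis of epigenetic variance
#'
#' Decomposes the normalized peak densities of one peak under the one-way
#' random-effects model \eqn{Y_{ij} = \mu + \alpha_i + \epsilon_{ij}}, where
#' \eqn{\alpha_i} is the species effect with variance \eqn{\sigma^2_\alpha}
#' and \eqn{\epsilon_{ij}} the individual effect with variance
#' \eqn{\sigma^2_\epsilon}. Returns the between/within sums of squares and
#' degrees of freedom, the natural estimates \eqn{S^2 = SS_w/df_w} of
#' \eqn{\sigma^2_\epsilon} and \eqn{S^2_\alpha = (MS_b - S^2)/n_0} of
#' \eqn{\sigma^2_\alpha}, and the epi-FST statistic.
#'
#' The effective sample size defaults to the standard unbalanced one-way
#' value \eqn{n_0 = (N - \sum_i n_i^2/N)/(k-1)}; pass \code{n0} to override
#' it (e.g. to force a rounded published value).
#'
#' @param values numeric vector of densities, one per sample
#' @param speciesLabels species label per sample (>= 2 species, each with
#'   >= 2 samples)
#' @param n0 optional override for the effective sample size
#' @return an object of class \code{VarianceComponents}: a list with
#'   \code{ss_between}, \code{ss_within}, \code{df_between},
#'   \code{df_within}, \code{ms_between}, \code{s2}, \code{n0},
#'   \code{s2_alpha}, \code{epi_fst} (NA when 0/0-undefined),
#'   \code{group_means}, \code{grand_mean}, \code{n_i}
#' @examples
#' vc <- varianceComponents(c(0, 2, 4, 6), c("a", "a", "b", "b"))
#' vc$ss_between  # 16
#' vc$s2_alpha    # 7
#' @export
varianceComponents <- function(values, speciesLabels, n0 = NULL) {
    values <- as.numeric(values)
    if (length(values) != length(speciesLabels))
        stop("values and speciesLabels differ in length")
    st <- .anevaStats(matrix(values, nrow = 1L), speciesLabels, n0 = n0)
    out <- lapply(st, function(x) if (is.matrix(x)) x[1L, ] else
                  if (length(x) > 1L && !is.null(names(x))) x else x[1L])
    out$group_means <- st$group_means[1L, ]
    out$n_i <- st$n_i
    structure(out, class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
    cat("One-way variance components (ANEVA)\n")
    cat(sprintf("  SS_between = %.6g (df %d), SS_within = %.6g (df %d)\n",
                x$ss_between, x$df_between, x$ss_within, x$df_within))
    cat(sprintf("  S^2 = %.6g, n0 = %.6g, S^2_alpha = %.6g, epi-FST = %s\n",
                x$s2, x$n0, x$s2_alpha,
                if (is.na(x$epi_fst)) "undefined" else
                    sprintf("%.6g", x$epi_fst)))
    invisible(x)
}

#' The epi-FST statistic from variance components
#'
#' The FST-like differentiation measure for epigenetic peak densities,
#' \eqn{\sigma^2_\alpha / (\sigma^2_\alpha + \sigma^2_\epsilon)}, estimated
#' by \eqn{S^2_\alpha / (S^2_\alpha + S^2)}. Negative values (when
#' \eqn{MS_{between} < S^2}) are retained, never clamped; the attainable
#' range is \eqn{[-1/(n_0-1), 1]}. When \eqn{S^2_\alpha + S^2 = 0} (constant
#' data) the statistic is undefined and \code{NA} is returned.
#'
#' @param vc a \code{VarianceComponents} object
#' @return the statistic, or \code{NA} when undefined
#' @export
epiFst <- function(vc) {
    stopifnot(inherits(vc, "VarianceComponents"))
    denom <- vc$s2_alpha + vc$s2
    if (denom == 0) NA_real_ else vc$s2_alpha / denom
}

#' Minimum attainable epi-FST for a given effective sample size
#'
#' The infimum of epi-FST over data configurations with zero between-species
#' mean square and positive within-species variance: there
#' \eqn{S^2_\alpha = -S^2/n_0} and the statistic equals \eqn{-1/(n_0 - 1)}.
#' It is monotone increasing in \eqn{n_0} and tends to 0 as
#' \eqn{n_0 \to \infty}; at \eqn{n_0 = 6} it equals \eqn{-0.2}.
#'
#' @param n0 effective sample size, > 1
#' @return \eqn{-1/(n_0-1)}
#' @examples
#' minEpiFst(6)  # -0.2
#' @export
minEpiFst <- function(n0) {
    if (any(n0 <= 1)) stop("n0 must be > 1")
    -1 / (n0 - 1)
}

## all distinct assignments of the multiset of labels g to positions,
## as an integer matrix n x M of level codes (exhaustive permutation space)
.allLabelAssignments <- function(g) {
    g <- factor(g)
    n <- length(g)
    if (n > 12L) stop("exhaustive enumeration supported for <= 12 samples")
    counts <- as.integer(table(g))
    rec <- function(positions, counts) {
        lev <- which(counts > 0)
        if (length(lev) == 1L) {
            m <- matrix(0L, length(positions), 1L)
            m[, 1L] <- lev
            rownames(m) <- as.character(positions)
            return(m)
        }
        l1 <- lev[1L]
        picks <- utils::combn(seq_along(positions), counts[l1], simplify = FALSE)
        cols <- lapply(picks, function(p) {
            rest <- rec(positions[-p], `[<-`(counts, l1, 0L))
            out <- matrix(0L, length(positions), ncol(rest))
            out[p, ] <- l1
            out[-p, ] <- rest
            out
        })
        do.call(cbind, cols)
    }
    asn <- rec(seq_len(n), counts)
    attr(asn, "levels") <- levels(g)
    asn
}

## epi-FST for each column of an assignment matrix (level codes), given y
.fstForAssignments <- function(y, asn, k, n0 = NULL) {
    n <- length(y)
    N <- n
    M <- ncol(asn)
    stats_ <- numeric(M)
    for (m in seq_len(M)) {
        gcodes <- asn[, m]
        gs <- rowsum(y, gcodes)            # k x 1 group sums
        ni <- tabulate(gcodes, nbins = k)
        gm <- gs[, 1L] / ni
        grand <- sum(y) / N
        ssb <- sum(ni * (gm - grand)^2)
        ssw <- sum(y * y) - sum(ni * gm^2)
        s2 <- max(ssw, 0) / (N - k)
        n0eff <- if (is.null(n0)) (N - sum(ni^2) / N) / (k - 1L) else n0
        s2a <- (ssb / (k - 1L) - s2) / n0eff
        stats_[m] <- if (s2a + s2 == 0) NA_real_ else s2a / (s2a + s2)
    }
    stats_
}

#' Permutation significance of the per-peak epi-FST
#'
#' Shuffles individuals' species labels uniformly at random (group sizes
#' preserved), recomputes epi-FST for each shuffle, and reports
#' \eqn{p = (r + 1)/(n_{perm} + 1)} where \eqn{r} is the number of permuted
#' statistics at least as large as the observed one. Permuted statistics
#' that are undefined (constant permuted data) count as not-as-extreme.
#' When the observed statistic itself is undefined, \eqn{p = 1} is reported
#' with \code{observed_defined = FALSE}.
#'
#' With \code{exhaustive = TRUE} (<= 12 samples) every distinct label
#' assignment is enumerated exactly once instead of sampling, and
#' \eqn{n_{perm}} is the number of assignments.
#'
#' @param values densities for one peak
#' @param speciesLabels species label per sample
#' @param nPerm number of random permutations (ignored when exhaustive)
#' @param seed optional integer seed for reproducibility
#' @param exhaustive enumerate the full permutation space instead of sampling
#' @param n0 optional effective-sample-size override, passed through
#' @return a list of class \code{PermutationResult}: \code{observed_epi_fst},
#'   \code{observed_defined}, \code{n_permutations}, \code{n_as_extreme},
#'   \code{p_value}
#' @export
permutationTest <- function(values, speciesLabels, nPerm = 10000L,
                            seed = NULL, exhaustive = FALSE, n0 = NULL) {
    if (!exhaustive && nPerm < 1L) stop("nPerm must be >= 1")
    y <- as.numeric(values)
    g <- factor(speciesLabels)
    obs <- .anevaStats(matrix(y, nrow = 1L), g, n0 = n0)$epi_fst
    if (!is.null(seed)) set.seed(seed)
    k <- nlevels(g)
    if (exhaustive) {
        asn <- .allLabelAssignments(g)
        perm <- .fstForAssignments(y, asn, k = k, n0 = n0)
        nPerm <- length(perm)
    } else {
        n <- length(y)
        idx <- vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))
        Yp <- matrix(y[idx], nrow = n)           # samples x nPerm
        gs <- rowsum(Yp, g)                      # k x nPerm group sums
        ni <- as.integer(table(g))
        gm <- sweep(gs, 1L, ni, "/")
        grand <- sum(y) / n
        ssb <- colSums(ni * (gm - grand)^2)
        ssw <- sum(y * y) - colSums(ni * gm^2)
        s2 <- pmax(ssw, 0) / (n - k)
        n0eff <- if (is.null(n0)) (n - sum(ni^2) / n) / (k - 1L) else n0
        s2a <- (ssb / (k - 1L) - s2) / n0eff
        denom <- s2a + s2
        perm <- ifelse(denom == 0, NA_real_, s2a / denom)
    }
    if (is.na(obs)) {
        res <- list(observed_epi_fst = NA_real_, observed_defined = FALSE,
                    n_permutations = as.integer(nPerm),
                    n_as_extreme = NA_integer_, p_value = 1)
    } else {
        r <- sum(perm >= obs, na.rm = TRUE)
        res <- list(observed_epi_fst = obs, observed_defined = TRUE,
                    n_permutations = as.integer(nPerm),
                    n_as_extreme = as.integer(r),
                    p_value = (r + 1) / (nPerm + 1))
    }
    structure(res, class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
    cat(sprintf("epi-FST = %s, p = %.4g (%d of %d permutations as extreme)\n",
                if (x$observed_defined) sprintf("%.4g", x$observed_epi_fst)
                else "undefined",
                x$p_value,
                if (is.na(x$n_as_extreme)) 0L else x$n_as_extreme,
                x$n_permutations))
    invisible(x)
}

#' Per-peak ANEVA table for a PeakMatrix
#'
#' Runs the variance decomposition for every peak, optionally restricted to a
#' subset of species (e.g. the human/chimp comparison of a three-species
#' matrix), and optionally attaches permutation p-values and their
#' Benjamini-Hochberg adjustment. Per-species within sums of squares and
#' variances (\code{ss_within_<species>}, \code{var_within_<species>}) are
#' included: they decompose \code{ss_within} exactly.
#'
#' @param pm a \code{\linkS4class{PeakMatrix}}
#' @param speciesSet optional character vector of species to use (default:
#'   all species in the metadata)
#' @param nPerm permutations per peak for the significance test (0 = skip)
#' @param seed integer seed governing all permutations (per-peak substreams
#'   are drawn sequentially from this one seed)
#' @param n0 optional effective-sample-size override
#' @param adjust add a BH-adjusted p-value column (\code{padj}) when
#'   permutations are run
#' @return a \code{DataFrame}, one row per peak, with columns
#'   \code{peak_id}, \code{ss_between}, \code{ss_within}, \code{df_between},
#'   \code{df_within}, \code{ms_between}, \code{s2}, \code{n0},
#'   \code{s2_alpha}, \code{epi_fst}, \code{fst_defined}, per-species
#'   \code{ss_within_*}/\code{var_within_*}, and (with permutations)
#'   \code{n_perm}, \code{n_as_extreme}, \code{p_value}, \code{padj}
#' @export
anevaTable <- function(pm, speciesSet = NULL, nPerm = 0L, seed = NULL,
                       n0 = NULL, adjust = TRUE) {
    stopifnot(is(pm, "PeakMatrix"))
    if (!is.null(speciesSet)) pm <- subsetSpecies(pm, speciesSet)
    Y <- densities(pm)
    g <- factor(species(pm))
    st <- .anevaStats(Y, g, n0 = n0)
    out <- DataFrame(peak_id = peakIds(pm),
                     ss_between = st$ss_between, ss_within = st$ss_within,
                     df_between = st$df_between, df_within = st$df_within,
                     ms_between = st$ms_between, s2 = st$s2, n0 = st$n0,
                     s2_alpha = st$s2_alpha, epi_fst = st$epi_fst,
                     fst_defined = !is.na(st$epi_fst))
    wsv <- .withinSpeciesStats(Y, g)
    for (sp in levels(g)) {
        out[[paste0("ss_within_", sp)]] <- wsv$ss[, sp]
        out[[paste0("var_within_", sp)]] <- wsv$var[, sp]
    }
    if (nPerm > 0L) {
        if (!is.null(seed)) set.seed(seed)
        pv <- numeric(nrow(Y))
        rv <- integer(nrow(Y))
        for (i in seq_len(nrow(Y))) {
            pr <- permutationTest(Y[i, ], g, nPerm = nPerm, seed = NULL,
                                  n0 = n0)
            pv[i] <- pr$p_value
            rv[i] <- if (is.na(pr$n_as_extreme)) NA_integer_ else pr$n_as_extreme
        }
        out$n_perm <- as.integer(nPerm)
        out$n_as_extreme <- rv
        out$p_value <- pv
        if (adjust) out$padj <- stats::p.adjust(pv, method = "BH")
    }
    metadata(out) <- list(species = levels(g), n_i = st$n_i, n0 = st$n0)
    out
}
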