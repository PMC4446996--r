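## Independent textbook oracles the implementation is checked against.
## These deliberately use different code paths (stats::lm/anova, rank
## formulas, explicit enumeration) than the package.

## one-way ANOVA via lm/anova: SS, df, MS for a single response
anovaOracle <- function(y, g) {
    fit <- stats::anova(stats::lm(y ~ factor(g)))
    list(ss_between = fit$`Sum Sq`[1L], ss_within = fit$`Sum Sq`[2L],
         df_between = fit$Df[1L], df_within = fit$Df[2L],
         ms_between = fit$`Mean Sq`[1L], s2 = fit$`Mean Sq`[2L])
}

## epi-FST recomputed from scratch with scalar arithmetic
fstOracle <- function(y, g, n0 = NULL) {
    g <- factor(g)
    ni <- as.integer(table(g))
    N <- length(y); k <- nlevels(g)
    gm <- tapply(y, g, mean)
    grand <- mean(y)
    ssb <- sum(ni * (gm - grand)^2)
    ssw <- sum((y - gm[as.integer(g)])^2)
    s2 <- ssw / (N - k)
    if (is.null(n0)) n0 <- (N - sum(ni^2) / N) / (k - 1)
    s2a <- (ssb / (k - 1) - s2) / n0
    if (s2a + s2 == 0) NA_real_ else s2a / (s2a + s2)
}

## exhaustive permutation p-value by explicit enumeration of all distinct
## label orderings (small n only): unique permutations of the label vector
exhaustivePermOracle <- function(y, g) {
    g <- as.character(g)
    n <- length(y)
    perms <- function(v) {
        if (length(v) == 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
        out
    }
    all <- unique(perms(g))
    obs <- fstOracle(y, g)
    stats_ <- vapply(all, function(lbl) fstOracle(y, lbl), numeric(1L))
    r <- sum(stats_ >= obs, na.rm = TRUE)
    list(n = length(all), p = (r + 1) / (length(all) + 1))
}

## Spearman rho from the average-rank definition
spearmanOracle <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## hypergeometric upper tail P(X >= m) by direct summation of the pmf
hyperTailOracle <- function(m, N, K, n) {
    i <- m:min(K, n)
    if (m > min(K, n)) return(0)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## covariance eigenanalysis oracle (divisor n), for small sample counts
pcaOracle <- function(X, nDivisor = nrow(X)) {
    Xc <- sweep(X, 2L, colMeans(X))
    C <- crossprod(Xc) / nDivisor
    e <- eigen(C, symmetric = TRUE)
    list(values = e$values, scores = Xc %*% e$vectors)
}

## small fixture: 3-species peak matrix with fixed densities
toyPeakMatrix <- function(nPeaks = 6L, seed = 42L,
                          sizes = c(human = 3L, chimp = 2L, macaque = 2L)) {
    set.seed(seed)
    sp <- rep(names(sizes), sizes)
    d <- matrix(abs(rnorm(nPeaks * sum(sizes), 10, 2)), nPeaks,
                dimnames = list(sprintf("pk%02d", seq_len(nPeaks)),
                                paste0("s", seq_len(sum(sizes)))))
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = seq(1L, by = 5000L, length.out = nPeaks),
                         width = 1000L))
    PeakMatrix(d, gr, species = sp)
}
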