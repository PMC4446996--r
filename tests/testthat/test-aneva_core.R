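test_that("variance components match hand algebra on worked examples", {
    vc <- varianceComponents(c(1, 1, 1, 3, 3, 3), rep(c("A", "B"), each = 3))
    expect_equal(vc$ss_between, 6)
    expect_equal(vc$ss_within, 0)
    expect_equal(vc$n0, 3)
    expect_equal(vc$s2, 0)
    expect_equal(vc$s2_alpha, 2)
    expect_equal(epiFst(vc), 1)  # all variation between species

    vc <- varianceComponents(c(1, 1, 1, 1), rep(c("A", "B"), each = 2))
    expect_equal(vc$ss_between, 0)
    expect_equal(vc$ss_within, 0)
    expect_equal(vc$s2_alpha, 0)
    expect_true(is.na(epiFst(vc)))  # 0/0: undefined, not zero

    vc <- varianceComponents(c(0, 2, 4, 6), rep(c("A", "B"), each = 2))
    expect_equal(vc$ss_between, 16)
    expect_equal(vc$ss_within, 4)
    expect_equal(vc$s2, 2)
    expect_equal(vc$n0, 2)
    expect_equal(vc$s2_alpha, 7)
    expect_equal(epiFst(vc), 7 / 9)

    # boundary of the attainable range: SS_between = 0, SS_within > 0
    vc <- varianceComponents(c(0, 2, 1, 1), rep(c("A", "B"), each = 2))
    expect_equal(vc$s2_alpha, -0.5)
    expect_equal(epiFst(vc), -1)
    expect_equal(epiFst(vc), minEpiFst(vc$n0))
})

test_that("degenerate designs are rejected", {
    expect_error(varianceComponents(1:3, c("A", "A", "B")), "fewer than 2")
    expect_error(varianceComponents(1:4, rep("A", 4)), "2 species")
    expect_error(minEpiFst(1), "n0 must be > 1")
})

test_that("SS/MS/df agree with the lm/anova oracle on random instances", {
    set.seed(101)
    designs <- list(c(11L, 4L), c(11L, 4L, 3L), c(2L, 2L), c(5L, 3L, 2L, 7L))
    for (rep_ in 1:250) {
        ni <- designs[[1L + (rep_ %% length(designs))]]
        g <- rep(letters[seq_along(ni)], ni)
        y <- rnorm(sum(ni), 10, 2) + rep(rnorm(length(ni), 0, 1), ni)
        vc <- varianceComponents(y, g)
        or <- anovaOracle(y, g)
        expect_equal(vc$ss_between, or$ss_between, tolerance = 1e-9)
        expect_equal(vc$ss_within, or$ss_within, tolerance = 1e-9)
        expect_identical(vc$df_between, or$df_between)
        expect_identical(vc$df_within, or$df_within)
        expect_equal(vc$ms_between, or$ms_between, tolerance = 1e-9)
        expect_equal(vc$s2, or$s2, tolerance = 1e-9)
        # conservation against a directly computed total SS
        expect_equal(vc$ss_between + vc$ss_within, sum((y - mean(y))^2),
                     tolerance = 1e-9)
    }
})

test_that("epi-FST respects its bounds and invariances", {
    set.seed(55)
    for (rep_ in 1:200) {
        ni <- sample(2:8, sample(2:4, 1L), replace = TRUE)
        g <- rep(letters[seq_along(ni)], ni)
        y <- rnorm(sum(ni), 5)
        vc <- varianceComponents(y, g)
        f <- epiFst(vc)
        expect_false(is.na(f))
        expect_lte(f, 1)
        expect_gte(f, minEpiFst(vc$n0) - 1e-12)
        # location/scale invariance: all SS scale by a^2, shifts cancel
        a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
        f2 <- epiFst(varianceComponents(a * y + b, g))
        expect_equal(f2, f, tolerance = 1e-8)
    }
    # epi-FST = 1 iff ss_within = 0 with ss_between > 0
    vc <- varianceComponents(c(2, 2, 5, 5), rep(c("A", "B"), each = 2))
    expect_equal(epiFst(vc), 1)
})

test_that("n0 override reproduces a forced effective sample size", {
    y <- c(rnorm(11, 10), rnorm(4, 12))
    g <- rep(c("h", "c"), c(11, 4))
    std <- varianceComponents(y, g)
    expect_equal(std$n0, 88 / 15)  # (15 - (121+16)/15) / 1
    forced <- varianceComponents(y, g, n0 = 6)
    expect_equal(forced$n0, 6)
    expect_equal(forced$s2_alpha, (std$ms_between - std$s2) / 6)
})

test_that("permutation p matches the exhaustive enumeration oracle", {
    y <- c(0, 0, 10, 10)
    g <- rep(c("A", "B"), each = 2)
    pt <- permutationTest(y, g, exhaustive = TRUE)
    or <- exhaustivePermOracle(y, g)
    # oracle enumerates label orderings (4! = 24), the implementation
    # distinct assignments (C(4,2) = 6); the tail *proportions* coincide
    orTail <- (or$p * (or$n + 1) - 1) / or$n
    expect_equal(pt$n_as_extreme / pt$n_permutations, orTail)
    expect_equal(pt$p_value, (2 + 1) / (6 + 1))
    expect_identical(pt$n_as_extreme, 2L)

    # random sampling converges to the exhaustive tail within binomial error
    set.seed(77)
    y2 <- c(1.2, 3.4, 0.5, 2.2, 4.0, 1.9, 2.8)
    g2 <- rep(c("A", "B"), c(4, 3))
    ex <- permutationTest(y2, g2, exhaustive = TRUE)
    pexact <- ex$n_as_extreme / ex$n_permutations
    rnd <- permutationTest(y2, g2, nPerm = 10000L, seed = 123L)
    se <- sqrt(pexact * (1 - pexact) / 10000)
    expect_lt(abs(rnd$p_value - pexact), 4 * se + 2e-4)
})

test_that("constant data gives an undefined statistic and p = 1", {
    pt <- permutationTest(rep(2, 6), rep(c("A", "B"), each = 3), nPerm = 50)
    expect_false(pt$observed_defined)
    expect_true(is.na(pt$observed_epi_fst))
    expect_equal(pt$p_value, 1)
})

test_that("permutation results are reproducible under a fixed seed", {
    y <- rnorm(15, 10); g <- rep(c("h", "c"), c(11, 4))
    a <- permutationTest(y, g, nPerm = 200, seed = 42)
    b <- permutationTest(y, g, nPerm = 200, seed = 42)
    expect_identical(a$n_as_extreme, b$n_as_extreme)
})

test_that("anevaTable contracts: per-row conservation, subsetting, BH", {
    pm <- toyPeakMatrix(nPeaks = 10L)
    tab <- anevaTable(pm, nPerm = 50L, seed = 1L)
    expect_identical(nrow(tab), 10L)
    totals <- rowSums(sweep(densities(pm), 1, rowMeans(densities(pm)))^2)
    expect_equal(tab$ss_between + tab$ss_within, unname(totals),
                 tolerance = 1e-9)
    expect_equal(tab$s2, tab$ss_within / tab$df_within)
    expect_identical(tab$padj, p.adjust(tab$p_value, "BH"))

    # pairwise comparison uses only the two species' samples
    two <- anevaTable(pm, speciesSet = c("human", "chimp"))
    expect_identical(metadata(two)$species, c("chimp", "human"))
    expect_identical(sum(metadata(two)$n_i), 5L)
    manual <- varianceComponents(
        densities(pm)[1, species(pm) %in% c("human", "chimp")],
        species(pm)[species(pm) %in% c("human", "chimp")])
    expect_equal(two$ss_between[1], manual$ss_between)

    expect_error(anevaTable(pm, speciesSet = "bonobo"), "unknown species")
})

test_that("natural estimators recover generating variances (unbiasedness)", {
    pm <- simulatePeakMatrix(simulationParams(
        nPeaks = 4000L, sigma2Alpha = 1, sigma2Eps = 1,
        speciesSizes = c(human = 11L, chimp = 4L), seed = 31L))
    tab <- anevaTable(pm)
    # MC standard errors at 4000 peaks
    seS2 <- sd(tab$s2) / sqrt(nrow(tab))
    seA <- sd(tab$s2_alpha) / sqrt(nrow(tab))
    expect_lt(abs(mean(tab$s2) - 1), 3 * seS2)
    expect_lt(abs(mean(tab$s2_alpha) - 1), 3 * seA)
})

test_that("permutation power rises with the variance ratio", {
    rates <- vapply(c(0.5, 2, 8), function(s2a) {
        pm <- simulatePeakMatrix(simulationParams(
            nPeaks = 120L, sigma2Alpha = s2a, sigma2Eps = 1,
            speciesSizes = c(h = 6L, c = 6L), seed = 91L))
        tab <- anevaTable(pm, nPerm = 200L, seed = 17L)
        mean(tab$p_value < 0.05)
    }, numeric(1L))
    expect_true(all(diff(rates) > 0))
})
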