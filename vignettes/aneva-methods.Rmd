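---
title: "Analysis of epigenetic variance: models, conventions and design notes"
author: "epiFST maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of epigenetic variance: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiFST)
```

# The model

`epiFST` treats one epigenetic peak at a time as a one-way random-effects
design. The normalized density of individual $j$ in species $i$ is

$$Y_{ij} = \mu + \alpha_i + \epsilon_{ij},$$

where $\alpha_i$ is a random species effect with variance
$\sigma^2_\alpha$ and $\epsilon_{ij}$ a random individual effect with
variance $\sigma^2_\epsilon$; all effects are additive. The total sum of
squares splits exactly into between- and within-species parts,

$$SS_{total} = \sum_i n_i(\bar y_{i\cdot} - \bar y)^2
             + \sum_i \sum_j (y_{ij} - \bar y_{i\cdot})^2
             = SS_{between} + SS_{within},$$

and the method-of-moments ("natural") estimates of the two components are

$$S^2 = \frac{SS_{within}}{N - k}, \qquad
  S^2_\alpha = \frac{MS_{between} - S^2}{n_0}, \qquad
  n_0 = \frac{N - \sum_i n_i^2 / N}{k - 1},$$

with $N$ the total sample count and $k$ the number of species. The
per-peak differentiation statistic is the intraclass-correlation form

$$\mathrm{epi\text{-}F_{ST}} = \frac{S^2_\alpha}{S^2_\alpha + S^2},$$

the ANOVA analogue of the classical population-genetic $F_{ST}$
($\Phi$-statistic). `varianceComponents()` returns all of these;
`anevaTable()` vectorizes them over a `PeakMatrix`.

Assumptions worth stating: densities are exchangeable within species,
effects are additive on the density scale, and the method is entirely
moment-based — no distributional assumption is needed for the estimates
themselves, only for their sampling behavior.

## Range of the statistic, and a documented discrepancy

$S^2_\alpha$ may be negative (whenever $MS_{between} < S^2$), so the
statistic can be negative. Algebraically its attainable range is
$[-1/(n_0 - 1),\, 1]$:

* the maximum 1 occurs when $SS_{within} = 0$ with $SS_{between} > 0$
  (all variation between species);
* the minimum $-1/(n_0 - 1)$ occurs when $MS_{between} = 0$ with
  $S^2 > 0$, where $S^2_\alpha = -S^2/n_0$.

Descriptions of this statistic sometimes attach the minimum to the
"$SS_{within} = 0$" configuration; under the estimators above that
configuration gives $+1$, not the minimum. `epiFST` follows the algebra:
`minEpiFst(n0)` returns $-1/(n_0-1)$, which is monotone increasing in
$n_0$ and tends to $0$ as $n_0 \to \infty$; at $n_0 = 6$ it equals exactly
$-0.2$.

## The effective sample size and its override

For an 11 + 4 two-species design the standard unbalanced formula gives
$n_0 = (15 - (121+16)/15)/1 = 88/15 \approx 5.867$, not the round 6 that
is sometimes quoted for this design. Because published analyses may have
rounded (or used another convention), every entry point that computes
variance components accepts an `n0` override so a stated value can be
forced; the default is always the standard formula. The corresponding
minima differ slightly: $-1/(88/15-1) \approx -0.2055$ versus $-0.2$.

## Degenerate peaks

When a peak is constant across all samples, $S^2_\alpha + S^2 = 0$ and the
statistic is $0/0$. It is reported as `NA` with `fst_defined = FALSE`,
never coerced to 0: a constant peak carries no information about
differentiation, and silently scoring it 0 would drag per-gene averages
toward "no divergence". Downstream averaging (`geneScores()`) drops
undefined peaks and flags the gene as `partial`.

# Permutation significance

Significance of a peak's statistic is assessed by shuffling individuals'
species labels uniformly at random (group sizes preserved), recomputing
the statistic, and reporting

$$p = \frac{r + 1}{n_{perm} + 1},$$

where $r$ counts permuted statistics $\ge$ the observed one. The $+1$
correction keeps $p > 0$ at any finite permutation count. Permuted
statistics that are undefined count as not-as-extreme; an undefined
observed statistic reports $p = 1$ with a flag. For $\le 12$ samples an
exhaustive mode enumerates every distinct label assignment exactly once,
which the tests use as their oracle. Within `anevaTable()` the per-peak
permutations are drawn sequentially from one seeded stream, so a single
seed reproduces the whole table; whether a shared or per-peak permutation
schedule is preferable is not settled anywhere authoritative, and the
independent-per-peak choice is the conservative default.

# Gene-level aggregation

A peak belongs to a gene when its interval overlaps the gene body extended
by 50 kb (default) on both ends. Any-overlap is the intersection rule used
because no containment definition is canonical and boundary-spanning peaks
should not be dropped; a midpoint-containment mode exists for sensitivity
checks. Flanks are strand-ignorant — both ends are extended equally, so
strand-aware flanking would change nothing. Gene scores are unweighted
arithmetic means of the defined per-peak values (no width or density
weighting; nothing in the method motivates a particular weighting). The
same machinery averages the per-species within variances
$SS_s/(n_s - 1)$, whose $SS_s$ decompose $SS_{within}$ exactly.

# TSS proximity

A peak is "near a TSS" when it overlaps a window of $\pm$`windowBp`
(default 2000) around the TSS base; each peak counts at most once. The
window is symmetric around the TSS position itself, so `windowBp = 0`
degenerates to overlap with the exact TSS coordinate. In `unique` mode the
TSS of the longest transcript represents the gene (ties broken by the
smallest coordinate — deterministic where a tie rule is otherwise
unspecified); `all` mode uses every known TSS, which can only increase the
near-TSS fraction.

# PCA conventions

`genomePca()` is a centered, **unscaled** PCA with samples as
observations and peaks as variables — an eigenanalysis of the covariance
matrix, so the eigenvalue sum equals the total variance (inertia) of the
centered data. Conventions:

* covariance divisor $n$ (the sample count), matching the inertia
  convention of centered-PCA frameworks; configurable to $n - 1$, which
  rescales eigenvalues but not their ratios or any distance;
* computation by SVD of the centered matrix (numerically safer than
  forming the peak-by-peak covariance);
* per-axis sign fixed by forcing the largest-magnitude loading positive,
  making scores reproducible across eigensolvers. Centroid distances are
  sign-free anyway, since both centroids flip together.

The center of a species' "ellipse of dispersion" is its samples' mean
score; ellipse shape is never needed for distances. Distances default to
the first 2 components (divergence plots are 2-D; the dimensionality used
for published distances is not stated anywhere, so this is a documented
choice — configurable).

Sliding windows are `windowBp` wide every `stepBp` (defaults 1 Mb / 100
kb); a chromosome shorter than one window yields a single truncated
window. Each window's PCA is re-centered on the window's own peaks, and
windows with fewer than `minPeaks = 2` peaks are reported with `NA`
distances (a single peak gives a rank-1 covariance with meaningless axes).

# Covariate correlations and enrichment

Spearman rank correlations (average-rank ties, large-sample p) relate SNP
counts per window to peak counts and mean densities. Because sliding
windows overlap, SNP-interval counts are attributed to windows
proportionally to overlap fraction — point-assignment would double-count
ambiguously, while proportional attribution is deterministic and additive.

Over-representation of differentially expressed genes among the top-$k$
genes (ranked by score, ties broken by higher peak count then gene id) is
tested with the one-sided hypergeometric (Fisher upper-tail) probability —
the standard choice for top-$k$ over-representation, since the test behind
published enrichment p-values of this kind is typically unstated. A
label-permutation alternative (`method = "permutation"`) probes robustness
to that choice. The universe is restricted to genes with defined scores
(intersected with a user universe when given), mirroring how
cross-dataset comparisons restrict to shared genes. DE lists are consumed
as input; no expression analysis is performed here.

# The simulator: a stated world

`simulatePeakMatrix()` draws $\alpha_i \sim N(0, \sigma^2_\alpha)$ and
$\epsilon_{ij} \sim N(0, \sigma^2_\epsilon)$ and truncates
$Y_{ij} = \mu + \alpha_i + \epsilon_{ij}$ at zero. Choices, made once:

* **Normality**: the model itself only fixes the first two moments;
  normal draws are the minimal completion that makes the ANOVA
  expectations exact, which is what the unbiasedness tests rely on.
* **Defaults**: species sizes {human 11, chimp 4, macaque 3} (the real
  three-species design's unbalancedness, deliberately stressing $n_0$ and
  degrees-of-freedom handling), $\mu = 10$, $\sigma^2_\alpha =
  \sigma^2_\epsilon = 1$, 1-kb peaks on a 2 × 50-Mb toy genome. With
  these, truncation at 0 touches far less than 1% of draws; if a
  parameter choice pushes past 1% the generator warns and records the
  clamped fraction, because truncation distorts the variance components.
* **Ground truth** (per-peak generating variances, divergent flag) rides
  in `rowData`, enabling parameter-recovery and calibration tests.

`simulateAnnotation()` tiles genes over the genome, gives each gene a
primary (longest-transcript) TSS plus 0–2 alternatives, draws a Poisson
SNP track, and samples DE labels with weight `divergentGeneBias` for genes
near divergent peaks — bias 1 is an exact null for the enrichment test.

What a green test establishes: that the estimators are unbiased, the
permutation and enrichment tests are calibrated, and the whole pipeline
recovers planted divergence *under this generative world*. Real peak
densities are not Gaussian, not independent across peaks, and their
normalization pipeline (never modeled here) induces sample-level
correlations; none of that is emulated, so green tests validate the
statistics' internals, not any biological claim.

# Numerical notes

* Sums of squares are computed from group sums; tiny negative
  $SS_{within}$ from cancellation is clamped at 0. Conservation
  ($SS_{between} + SS_{within} = SS_{total}$, and the per-species split of
  $SS_{within}$) is enforced in tests at $10^{-9}$ relative tolerance.
* Permutation tie comparison is plain `>=` on doubles; permuted and
  observed statistics come from the same code path, so exact ties are
  preserved.
* Coordinates: files follow the BED convention (0-based, half-open);
  in-memory objects are `GRanges` (1-based, closed), converted exactly at
  the I/O boundary. This is the standard Bioconductor arrangement and
  every boundary case (e.g. a peak starting exactly at the end of a
  flanked interval) behaves identically to a pure half-open
  implementation.
* Gene flanks are clamped at position 1 and, when sequence lengths are
  known, at the chromosome end.

# Limitations

* Two-level designs only: no hierarchical (population-within-species)
  decomposition.
* Moment estimators, not likelihood: $S^2_\alpha$ is unbiased but can be
  negative; no shrinkage across peaks is attempted.
* Normalization of densities is entirely upstream; the reader accepts any
  non-negative matrix and records nothing about how it was produced.
* Cross-assembly coordinate conversion (liftover) is out of scope; all
  peaks are assumed to live on one reference.
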