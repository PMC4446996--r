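#' @importFrom methods setClass setValidity setMethod new is validObject callNextMethod
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' PeakMatrix: peak intervals with per-sample normalized densities
#'
#' A \code{PeakMatrix} holds genomic peak intervals (as
#' \code{\link[GenomicRanges]{GRanges}}) together with one normalized density
#' value per sample per peak and a species label per sample. It extends
#' \code{\link[SummarizedExperiment]{RangedSummarizedExperiment}}: the single
#' assay is named \code{"density"}, row names are peak identifiers, and
#' \code{colData} carries a \code{species} factor.
#'
#' Densities are non-negative, dimensionless normalized peak densities; a peak
#' absent in a sample is density 0, never \code{NA}. How densities were
#' normalized upstream is the caller's responsibility and is not recorded.
#'
#' @slot ... inherited from \code{RangedSummarizedExperiment}.
#'
#' @seealso \code{\link{PeakMatrix}} (constructor), \code{\link{readPeakMatrix}}
#' @export
setClass("PeakMatrix", contains = "RangedSummarizedExperiment")

setValidity("PeakMatrix", function(object) {
    msg <- character(0)
    if (!("density" %in% assayNames(object)))
        msg <- c(msg, "assay 'density' is required")
    else {
        d <- assay(object, "density")
        if (anyNA(d))
            msg <- c(msg, "density matrix contains missing values (absent peaks must be 0)")
        else if (any(d < 0))
            msg <- c(msg, sprintf("negative density for peak '%s'",
                                  rownames(object)[which(rowSums(d < 0) > 0)[1L]]))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "peak ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!("species" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain a 'species' column")
    if (length(msg)) msg else TRUE
})

#' Construct a PeakMatrix
#'
#' @param density numeric matrix, peaks x samples, non-negative, no NAs.
#'   Row names are peak ids, column names sample ids (both required).
#' @param rowRanges \code{GRanges} of peak intervals, one per density row.
#' @param species character or factor of species labels, one per sample.
#'
#' @return A validated \code{\linkS4class{PeakMatrix}}.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), width = 100))
#' d <- matrix(runif(8), 2, 4,
#'             dimnames = list(c("pk1", "pk2"), paste0("s", 1:4)))
#' pm <- PeakMatrix(d, gr, species = c("human", "human", "chimp", "chimp"))
#' @export
PeakMatrix <- function(density, rowRanges, species) {
    density <- as.matrix(density)
    if (length(species) != ncol(density))
        stop("length(species) must equal ncol(density)")
    names(rowRanges) <- rownames(density)
    se <- SummarizedExperiment(
        assays = list(density = density),
        rowRanges = rowRanges,
        colData = DataFrame(species = as.character(species),
                            row.names = colnames(density)))
    new("PeakMatrix", se)
}

#' Accessors for PeakMatrix
#'
#' \code{densities} returns the peaks x samples density matrix; \code{species}
#' the per-sample species labels; \code{peakIds} the peak identifiers;
#' \code{speciesSizes} the per-species sample counts.
#'
#' @param x a \code{PeakMatrix}
#' @return see above
#' @rdname PeakMatrix-accessors
#' @export
densities <- function(x) assay(x, "density")

#' @rdname PeakMatrix-accessors
#' @export
species <- function(x) colData(x)$species

#' @rdname PeakMatrix-accessors
#' @export
peakIds <- function(x) rownames(x)

#' @rdname PeakMatrix-accessors
#' @export
speciesSizes <- function(x) table(species(x))

setMethod("show", "PeakMatrix", function(object) {
    cat(sprintf("PeakMatrix: %d peaks x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(species(object))
    cat("species:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
    cat("chromosomes:", paste(seqlevelsInUse(rowRanges(object)), collapse = ", "), "\n")
})

#' Subset a PeakMatrix to selected species
#'
#' @param x a \code{PeakMatrix}
#' @param keep character vector of species labels to retain
#' @param minSamples minimum samples per retained species (default 2; the
#'   variance decomposition needs within-species degrees of freedom)
#' @return a \code{PeakMatrix} with only samples of the requested species
#' @export
subsetSpecies <- function(x, keep, minSamples = 2L) {
    present <- unique(species(x))
    missing <- setdiff(keep, present)
    if (length(missing))
        stop("unknown species label(s): ", paste(missing, collapse = ", "))
    out <- x[, species(x) %in% keep]
    tab <- table(species(out))
    small <- names(tab)[tab < minSamples]
    if (length(small))
        stop("species with fewer than ", minSamples, " samples: ",
             paste(small, collapse = ", "))
    out
}
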