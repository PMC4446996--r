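#' Read a peak density matrix and sample metadata from TSV
#'
#' The matrix file has columns \code{peak_id chrom start end} followed by one
#' column per sample; coordinates on disk are 0-based half-open (BED
#' convention) and are converted to 1-based closed \code{GRanges} in memory.
#' The metadata file has columns \code{sample_id species}. The two sample sets
#' must be identical; rows are returned sorted by (chrom, start).
#'
#' @param matrixPath path to the peak matrix TSV
#' @param metadataPath path to the sample metadata TSV
#' @return a \code{\linkS4class{PeakMatrix}}
#' @export
readPeakMatrix <- function(matrixPath, metadataPath) {
    mat <- utils::read.delim(matrixPath, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    meta <- utils::read.delim(metadataPath, check.names = FALSE,
                              stringsAsFactors = FALSE, comment.char = "#")
    need <- c("peak_id", "chrom", "start", "end")
    if (!all(need %in% colnames(mat)))
        stop("peak matrix must have columns ", paste(need, collapse = ", "))
    if (!all(c("sample_id", "species") %in% colnames(meta)))
        stop("metadata must have columns sample_id, species")
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample_id in metadata: ",
             meta$sample_id[duplicated(meta$sample_id)][1L])
    sampleCols <- setdiff(colnames(mat), need)
    missingCols <- setdiff(meta$sample_id, sampleCols)
    if (length(missingCols))
        stop("sample(s) in metadata but absent from matrix: ",
             paste(missingCols, collapse = ", "))
    extraCols <- setdiff(sampleCols, meta$sample_id)
    if (length(extraCols))
        stop("sample column(s) absent from metadata: ",
             paste(extraCols, collapse = ", "))
    dup <- mat$peak_id[duplicated(mat$peak_id)]
    if (length(dup)) stop("duplicate peak_id: ", dup[1L])
    bad <- which(!(mat$start < mat$end))
    if (length(bad))
        stop(sprintf("start >= end for peak '%s' (row %d)",
                     mat$peak_id[bad[1L]], bad[1L]))
    if (any(mat$start < 0))
        stop("negative start coordinate for peak '",
             mat$peak_id[which(mat$start < 0)[1L]], "'")
    d <- as.matrix(mat[, meta$sample_id, drop = FALSE])
    if (anyNA(d)) {
        idx <- which(is.na(d), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing density for peak '%s', sample '%s'",
                     mat$peak_id[idx[1L]], meta$sample_id[idx[2L]]))
    }
    if (any(d < 0)) {
        idx <- which(d < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative density for peak '%s', sample '%s'",
                     mat$peak_id[idx[1L]], meta$sample_id[idx[2L]]))
    }
    rownames(d) <- mat$peak_id
    gr <- GRanges(mat$chrom, IRanges(start = mat$start + 1L, end = mat$end))
    o <- order(as.character(seqnames(gr)), start(gr))
    PeakMatrix(d[o, , drop = FALSE], gr[o], species = meta$species)
}

#' Write a PeakMatrix (and its metadata) to TSV
#'
#' Inverse of \code{\link{readPeakMatrix}}: coordinates are written 0-based
#' half-open. Densities are written at full precision so that a
#' write-then-read round trip is bit identical.
#'
#' @param pm a \code{PeakMatrix}
#' @param matrixPath,metadataPath output paths (metadata optional)
#' @return \code{matrixPath}, invisibly
#' @export
writePeakMatrix <- function(pm, matrixPath, metadataPath = NULL) {
    gr <- rowRanges(pm)
    df <- data.frame(peak_id = peakIds(pm),
                     chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L,
                     end = end(gr),
                     check.names = FALSE)
    d <- densities(pm)
    for (s in colnames(d)) df[[s]] <- sprintf("%.17g", d[, s])
    utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(metadataPath))
        utils::write.table(data.frame(sample_id = colnames(pm),
                                      species = species(pm)),
                           metadataPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(matrixPath)
}

## diagnose a malformed BED line so errors carry a line number
.bedDiagnose <- function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    for (i in which(keep)) {
        f <- strsplit(lines[i], "\t")[[1L]]
        if (length(f) < 3 ||
            is.na(suppressWarnings(as.numeric(f[2L]))) ||
            is.na(suppressWarnings(as.numeric(f[3L]))))
            return(sprintf("malformed coordinates at line %d of %s: '%s'",
                           i, path, lines[i]))
    }
    NULL
}

#' Read a BED3/BED6 track as a typed GRanges
#'
#' BED is 0-based half-open on disk; the returned \code{GRanges} is 1-based
#' closed (standard \code{rtracklayer} conversion). \code{type} selects the
#' interpretation of the optional columns:
#' \describe{
#'   \item{\code{"genes"}}{name = gene id (unique, required); strand kept,
#'     \code{*} when absent.}
#'   \item{\code{"tss"}}{name = gene id (repeats allowed: one row per known
#'     TSS); score = transcript length, used by \code{\link{tssProximity}} to
#'     pick the unique (longest-transcript) TSS per gene; intervals are
#'     single positions.}
#'   \item{\code{"counts"}}{score = non-negative count per interval (e.g.
#'     SNPs); intervals within the track must not overlap.}
#' }
#'
#' @param path BED file path
#' @param type one of \code{"genes"}, \code{"tss"}, \code{"counts"}
#' @return \code{GRanges} with metadata columns per \code{type}
#' @export
readBed <- function(path, type = c("genes", "tss", "counts")) {
    type <- match.arg(type)
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) {
                       diag <- .bedDiagnose(path)
                       stop(if (is.null(diag)) conditionMessage(e) else diag,
                            call. = FALSE)
                   })
    if (type == "genes") {
        if (is.null(gr$name) || anyNA(gr$name))
            stop("gene BED needs a name column (gene ids)")
        if (anyDuplicated(gr$name))
            stop("duplicate gene_id: ", gr$name[duplicated(gr$name)][1L])
        mcols(gr) <- DataFrame(gene_id = gr$name)
    } else if (type == "tss") {
        if (is.null(gr$name) || anyNA(gr$name))
            stop("TSS BED needs a name column (gene ids)")
        tx_length <- if (is.null(gr$score)) rep(NA_real_, length(gr)) else gr$score
        mcols(gr) <- DataFrame(gene_id = gr$name, tx_length = tx_length)
    } else {
        count <- if (is.null(gr$score)) rep(1, length(gr)) else gr$score
        if (any(count < 0)) stop("counts must be non-negative")
        if (sum(width(IRanges::reduce(gr))) < sum(width(gr)))
            stop("count track intervals overlap within the track")
        mcols(gr) <- DataFrame(count = count)
    }
    gr
}

#' @rdname readBed
#' @param gr a GRanges produced by this package; the typed columns
#'   \code{gene_id}, \code{tx_length} and \code{count} are mapped back onto
#'   the BED name/score fields
#' @export
writeBed <- function(gr, path) {
    mc <- mcols(gr)
    if (is.null(mc$name) && !is.null(mc$gene_id)) mc$name <- mc$gene_id
    if (is.null(mc$score)) {
        if (!is.null(mc$tx_length)) mc$score <- mc$tx_length
        else if (!is.null(mc$count)) mc$score <- mc$count
    }
    keep <- intersect(c("name", "score"), colnames(mc))
    mcols(gr) <- mc[, keep, drop = FALSE]
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read chromosome sizes from a two-column TSV (chrom, length)
#' @param path TSV path, no header
#' @return named integer vector of chromosome lengths
#' @export
readChromSizes <- function(path) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("chrom sizes file needs two columns: chrom, length")
    stats::setNames(as.integer(df[[2L]]), df[[1L]])
}

#' Write a result table to TSV
#'
#' Writes any of the package's result tables (\code{DataFrame} or
#' \code{data.frame}) with a header row, floats at fixed precision
#' (\code{digits} significant digits) and deterministic row order (rows are
#' written as given). Optional \code{header} lines are written first as
#' \code{#}-prefixed comments, which \code{\link{readResults}} skips.
#'
#' @param x result table
#' @param path output path
#' @param digits significant digits for numeric columns (default 10)
#' @param header optional character vector of provenance comment lines
#' @return \code{path}, invisibly
#' @export
writeResults <- function(x, path, digits = 10, header = NULL) {
    df <- as.data.frame(x)
    num <- vapply(df, is.double, logical(1L))
    df[num] <- lapply(df[num], function(v) {
        out <- sprintf(paste0("%.", digits, "g"), v)
        out[is.na(v)] <- "NA"
        out
    })
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header))
        writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE)
}
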