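#' @include AllClasses.R utils.R
NULL

#' Read a nuclear/cytoplasmic fraction count matrix
#'
#' Expects a TSV with a \code{gene_id} column followed by one column
#' per library named \code{<cellline>_<fraction>} with fraction
#' \code{cytoplasm} or \code{nucleus}. Library sizes default to
#' column sums.
#'
#' @param path path to the TSV.
#' @param librarySizes optional named numeric vector of total mapped
#'   reads per library.
#' @return A \code{SummarizedExperiment} with assay \code{counts} and
#'   colData columns \code{cell_line}, \code{fraction},
#'   \code{library_size}.
#' @export
readFractionCounts <- function(path, librarySizes = NULL) {
    df <- .readTsv(path)
    if (!"gene_id" %in% colnames(df))
        .stopf("counts table must have a gene_id column")
    m <- as.matrix(df[, setdiff(colnames(df), "gene_id"), drop = FALSE])
    rownames(m) <- df$gene_id
    fractionCounts(m, librarySizes = librarySizes)
}

#' Build a fraction-counts container from a matrix
#'
#' @param counts integer matrix, genes x libraries, column names
#'   \code{<cellline>_<fraction>}.
#' @param librarySizes optional named numeric vector per library
#'   (defaults to column sums).
#' @return A \code{SummarizedExperiment}; see
#'   \code{\link{readFractionCounts}}.
#' @export
fractionCounts <- function(counts, librarySizes = NULL) {
    libs <- colnames(counts)
    frac <- sub("^.*_", "", libs)
    cell <- sub("_[^_]*$", "", libs)
    if (!all(frac %in% c("cytoplasm", "nucleus")))
        .stopf("library names must end in _cytoplasm or _nucleus")
    if (is.null(librarySizes)) librarySizes <- colSums(counts)
    if (any(librarySizes <= 0))
        .stopf("library '%s' has zero library size",
               libs[which(librarySizes <= 0)[1]])
    for (cl in unique(cell)) {
        have <- sort(unique(frac[cell == cl]))
        if (!identical(have, c("cytoplasm", "nucleus")))
            .stopf("cell line '%s' is missing a %s fraction", cl,
                   setdiff(c("cytoplasm", "nucleus"), have))
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(cell_line = cell, fraction = frac,
                                       library_size = unname(librarySizes[libs]),
                                       row.names = libs))
}

#' Classify genes as cytoplasmic
#'
#' Each library is scaled to counts per million by its library size;
#' the normalized cytoplasm/nucleus ratio of a gene is the pooled CPM
#' sum over all cytoplasmic libraries (plus a pseudocount) divided by
#' the pooled nuclear CPM sum (plus the pseudocount). A gene is
#' cytoplasmic when that ratio exceeds 1 AND its total raw read count
#' over all libraries reaches \code{minTotalReads} (low-abundance
#' genes give unreliable ratios). With \code{perLineMedian = TRUE}
#' the ratio is the median of per-cell-line ratios instead of the
#' pooled ratio.
#'
#' @param se a \code{SummarizedExperiment} from
#'   \code{\link{fractionCounts}}.
#' @param minTotalReads minimum raw reads across all libraries
#'   (default 20).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param perLineMedian use the median of per-cell-line ratios.
#' @return data.frame with \code{gene_id}, \code{total_reads},
#'   \code{normalized_ratio}, \code{passed_depth_filter},
#'   \code{is_cytoplasmic}.
#' @export
classifyLocalization <- function(se, minTotalReads = 20L,
                                 pseudocount = 0.5,
                                 perLineMedian = FALSE) {
    counts <- SummarizedExperiment::assay(se, "counts")
    cd <- SummarizedExperiment::colData(se)
    if (any(cd$library_size <= 0)) .stopf("zero library size")
    cpm <- sweep(counts, 2, cd$library_size, "/") * 1e6
    cyt <- cd$fraction == "cytoplasm"
    if (perLineMedian) {
        lines <- unique(cd$cell_line)
        rat <- sapply(lines, function(cl) {
            ic <- which(cd$cell_line == cl & cyt)
            inn <- which(cd$cell_line == cl & !cyt)
            (rowSums(cpm[, ic, drop = FALSE]) + pseudocount) /
                (rowSums(cpm[, inn, drop = FALSE]) + pseudocount)
        })
        ratio <- apply(rat, 1, stats::median)
    } else {
        ratio <- (rowSums(cpm[, cyt, drop = FALSE]) + pseudocount) /
            (rowSums(cpm[, !cyt, drop = FALSE]) + pseudocount)
    }
    total <- rowSums(counts)
    passed <- total >= minTotalReads
    data.frame(gene_id = rownames(counts),
               total_reads = unname(total),
               normalized_ratio = unname(ratio),
               passed_depth_filter = unname(passed),
               is_cytoplasmic = unname(passed & ratio > 1),
               stringsAsFactors = FALSE)
}

#' Intersect a gene set with the cytoplasmic calls
#'
#' @param models a \linkS4class{TranscriptModels} (e.g. the
#'   intergenic lncRNA set).
#' @param calls localization calls from
#'   \code{\link{classifyLocalization}}.
#' @return A \linkS4class{TranscriptModels} restricted to cytoplasmic
#'   genes, sorted by gene id.
#' @export
intersectCytoplasmic <- function(models, calls) {
    cyto <- calls$gene_id[calls$is_cytoplasmic]
    subsetByGenes(models, sort(intersect(models@genes$gene_id, cyto)))
}
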