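#' @include AllClasses.R
#' @importFrom utils head tail read.table write.table packageVersion
#' @importFrom stats runif rnbinom pbinom median setNames
#' @importFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

## reverse complement of an RNA or DNA string, returned as DNA
.revcompDNA <- function(x) {
    x <- chartr("Uu", "Tt", x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.rnaToDna <- function(x) chartr("U", "T", toupper(x))

.dnaToRna <- function(x) chartr("T", "U", toupper(x))

## split "species.chrom" at the first dot
.splitMafSrc <- function(src) {
    sp <- sub("\\..*$", "", src)
    chrom <- sub("^[^.]*\\.", "", src)
    cbind(species = sp, chrom = chrom)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

.readTsv <- function(path, ...) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msg <- function(verbose, fmt, ...) {
    if (verbose) message(sprintf(fmt, ...))
}
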