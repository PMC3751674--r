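#' @include AllClasses.R utils.R
NULL

#' Read a species-to-clade table
#'
#' Expects a TSV with columns \code{species} and \code{clade}; clade
#' labels are the disjoint finest groups \code{primate},
#' \code{mammal} (non-primate placental mammals) and \code{vertebrate}
#' (non-mammal vertebrates). The tiers used for conservation calls are
#' nested: the mammal tier includes the primates, the vertebrate tier
#' includes everything.
#'
#' @param path path to the TSV.
#' @param reference reference species; defaults to the first primate
#'   listed.
#' @return data.frame with columns \code{species}, \code{clade} and a
#'   \code{"reference"} attribute.
#' @export
readCladeTable <- function(path, reference = NULL) {
    df <- .readTsv(path)
    if (!all(c("species", "clade") %in% colnames(df)))
        .stopf("clade table must have columns species, clade")
    if (!all(df$clade %in% CLADE_LEVELS))
        .stopf("clade labels must be one of %s",
               paste(CLADE_LEVELS, collapse = ", "))
    if (is.null(reference)) {
        pri <- df$species[df$clade == "primate"]
        if (length(pri) == 0) .stopf("clade table lists no primate species")
        reference <- pri[1]
    }
    if (!reference %in% df$species)
        .stopf("reference species '%s' not in clade table", reference)
    if (df$clade[match(reference, df$species)] != "primate")
        .stopf("reference species '%s' must be a primate", reference)
    attr(df, "reference") <- reference
    df
}

#' Load and index a multiple alignment
#'
#' Parses a MAF file into a \linkS4class{MafIndex} supporting queries
#' by reference-genome interval. The first \code{s} row of every block
#' must be the reference species; its coordinates anchor the block on
#' the genome. When a genome FASTA is supplied, reference rows are
#' validated against it.
#'
#' @param maf path to the MAF file.
#' @param clades clade table from \code{\link{readCladeTable}} (or a
#'   data.frame with columns \code{species}, \code{clade}).
#' @param fasta optional genome FASTA for reference-row validation.
#' @param reference reference species; defaults to the clade table's
#'   \code{"reference"} attribute, else the first primate.
#' @return A \linkS4class{MafIndex}.
#' @export
loadMaf <- function(maf, clades, fasta = NULL, reference = NULL) {
    if (is.null(reference)) reference <- attr(clades, "reference")
    if (is.null(reference)) {
        pri <- clades$species[clades$clade == "primate"]
        if (length(pri) == 0) .stopf("clade table lists no primate species")
        reference <- pri[1]
    }
    lines <- readLines(maf)
    aIdx <- which(startsWith(lines, "a"))
    if (length(aIdx) == 0) .stopf("no alignment blocks found in %s", maf)
    sIdx <- which(startsWith(lines, "s"))
    fields <- strsplit(trimws(lines[sIdx]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 7L))
        .stopf("malformed MAF 's' line at line %d of %s",
               sIdx[which(nf != 7L)[1]], maf)
    m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
    src <- .splitMafSrc(m[, 2])
    species <- src[, "species"]
    unmapped <- setdiff(unique(species), clades$species)
    if (length(unmapped) > 0)
        .stopf("MAF species '%s' is not mapped in the clade table",
               unmapped[1])
    blockOf <- findInterval(sIdx, aIdx)
    texts <- toupper(m[, 7])
    starts <- as.integer(m[, 3])
    sizes <- as.integer(m[, 4])
    strands <- m[, 5]

    blocks <- vector("list", length(aIdx))
    ranges <- vector("list", length(aIdx))
    for (b in seq_along(aIdx)) {
        rows <- which(blockOf == b)
        if (length(rows) == 0)
            .stopf("alignment block at line %d of %s has no 's' rows",
                   aIdx[b], maf)
        if (species[rows[1]] != reference)
            .stopf("block at line %d: first row is '%s', expected reference '%s'",
                   aIdx[b], species[rows[1]], reference)
        if (strands[rows[1]] != "+")
            .stopf("block at line %d: reference row must be on the + strand",
                   aIdx[b])
        gl <- nchar(texts[rows])
        if (length(unique(gl)) != 1L)
            .stopf("block at line %d: rows have unequal gapped lengths", aIdx[b])
        reftext <- texts[rows[1]]
        refcols <- if (grepl("-", reftext, fixed = TRUE))
            which(strsplit(reftext, "", fixed = TRUE)[[1]] != "-") else NULL
        blocks[[b]] <- list(
            chrom = src[rows[1], "chrom"],
            start = starts[rows[1]],
            size = sizes[rows[1]],
            species = species[rows],
            texts = stats::setNames(texts[rows], species[rows]),
            refcols = refcols)
        ranges[[b]] <- c(starts[rows[1]], sizes[rows[1]])
    }
    chroms <- vapply(blocks, `[[`, character(1), "chrom")
    st <- vapply(blocks, `[[`, numeric(1), "start")
    sz <- vapply(blocks, `[[`, numeric(1), "size")
    blockRanges <- GenomicRanges::GRanges(
        chroms, IRanges::IRanges(start = st + 1L, width = sz))

    if (!is.null(fasta)) {
        genome <- Biostrings::readDNAStringSet(fasta)
        names(genome) <- sub("\\s.*$", "", names(genome))
        for (b in seq_along(blocks)) {
            blk <- blocks[[b]]
            if (!blk$chrom %in% names(genome))
                .stopf("MAF block contig '%s' absent from the FASTA", blk$chrom)
            want <- toupper(as.character(Biostrings::subseq(
                genome[[blk$chrom]], blk$start + 1L, blk$start + blk$size)))
            got <- gsub("-", "", blk$texts[[1]], fixed = TRUE)
            if (got != want)
                .stopf("MAF reference row disagrees with the FASTA at %s:%d-%d",
                       blk$chrom, blk$start + 1L, blk$start + blk$size)
        }
    }
    new("MafIndex", blocks = blocks, blockRanges = blockRanges,
        species = unique(species), reference = reference,
        clades = data.frame(species = clades$species, clade = clades$clade,
                            stringsAsFactors = FALSE))
}

#' Query an alignment index by reference interval
#'
#' Returns the per-species aligned (gapped) substrings over a
#' reference-genome interval, or an empty result when the interval is
#' not fully covered by one alignment block.
#'
#' @param index a \linkS4class{MafIndex}.
#' @param chrom reference contig.
#' @param start,end 0-based half-open reference interval.
#' @return Named character vector of gapped aligned strings (empty if
#'   unaligned).
#' @export
queryMaf <- function(index, chrom, start, end) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    hit <- GenomicRanges::findOverlaps(q, index@blockRanges, type = "within")
    if (length(hit) == 0) return(stats::setNames(character(0), character(0)))
    blk <- index@blocks[[S4Vectors::subjectHits(hit)[1]]]
    off1 <- start - blk$start + 1L
    off2 <- end - blk$start
    if (is.null(blk$refcols)) {
        c1 <- off1; c2 <- off2
    } else {
        c1 <- blk$refcols[off1]; c2 <- blk$refcols[off2]
    }
    stats::setNames(substring(blk$texts, c1, c2), names(blk$texts))
}
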