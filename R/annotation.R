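#' @include AllClasses.R utils.R
NULL

## map a 0-based genomic position to a 0-based transcript offset, given
## exon starts/ends (0-based half-open, ordered 5'->3' in transcript
## orientation) and the strand
.genomicToTx <- function(starts0, ends0, strand, gpos0) {
    cum <- 0L
    for (k in seq_along(starts0)) {
        if (gpos0 >= starts0[k] && gpos0 < ends0[k]) {
            off <- if (strand == "+") gpos0 - starts0[k]
                   else ends0[k] - 1L - gpos0
            return(cum + off)
        }
        cum <- cum + (ends0[k] - starts0[k])
    }
    NA_integer_
}

#' Read gene models from GTF and FASTA
#'
#' Parses a GENCODE-dialect GTF (gene/transcript/exon, optionally CDS,
#' with \code{gene_id}, \code{transcript_id}, \code{transcript_type}
#' attributes) together with the genome FASTA, and builds
#' \linkS4class{TranscriptModels}: exon structures ordered 5'->3' in
#' transcript orientation, spliced sense-strand sequences (minus-strand
#' transcripts reverse-complemented), and CDS/UTR region maps in
#' transcript coordinates where CDS features are present.
#'
#' @param gtf path to the GTF file (1-based inclusive coordinates).
#' @param fasta path to the genome FASTA.
#' @return A \linkS4class{TranscriptModels} object, transcripts and
#'   genes sorted by id.
#' @examples
#' gt <- generateDataset(simConfig(nLncrnaGenes = 5, nCodingGenes = 2,
#'                                 seedRng = 1), td <- tempfile())
#' models <- readGeneModels(file.path(td, "annotation.gtf"),
#'                          file.path(td, "genome.fa"))
#' models
#' @export
readGeneModels <- function(gtf, fasta) {
    gr <- rtracklayer::import(gtf, format = "gtf")
    genome <- Biostrings::readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))

    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$gene_id))
        .stopf("GTF is missing the required attribute 'gene_id'")
    types <- as.character(mc$type)
    ex <- gr[types == "exon"]
    if (length(ex) == 0L) .stopf("GTF contains no exon features")
    exmc <- S4Vectors::mcols(ex)
    if (is.null(exmc$transcript_id) || anyNA(exmc$transcript_id))
        .stopf("GTF exon features are missing the required attribute 'transcript_id'")
    if (is.null(exmc$transcript_type) || anyNA(exmc$transcript_type))
        .stopf("GTF exon features are missing the required attribute 'transcript_type'")

    chrom <- as.character(GenomicRanges::seqnames(ex))
    bad <- which(!(chrom %in% names(genome)))
    if (length(bad) > 0)
        .stopf("exon of transcript %s lies on contig '%s' absent from the FASTA",
               exmc$transcript_id[bad[1]], chrom[bad[1]])
    clen <- Biostrings::width(genome)[match(chrom, names(genome))]
    out <- which(GenomicRanges::start(ex) < 1L | GenomicRanges::end(ex) > clen)
    if (length(out) > 0)
        .stopf("exon of transcript %s at %s:%d-%d extends outside its FASTA contig",
               exmc$transcript_id[out[1]], chrom[out[1]],
               GenomicRanges::start(ex)[out[1]], GenomicRanges::end(ex)[out[1]])

    o <- order(exmc$transcript_id, GenomicRanges::start(ex))
    ex <- ex[o]
    exmc <- S4Vectors::mcols(ex)
    txid <- as.character(exmc$transcript_id)
    chrom <- as.character(GenomicRanges::seqnames(ex))

    ## genomic-order exon sequences, per contig
    pieces <- character(length(ex))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        pieces[idx] <- as.character(
            Biostrings::extractAt(genome[[ch]], IRanges::ranges(ex[idx])))
    }
    txf <- factor(txid, levels = sort(unique(txid)))
    splicedGenomic <- vapply(split(pieces, txf), paste0, character(1),
                             collapse = "")
    seqs <- Biostrings::DNAStringSet(splicedGenomic)

    fi <- match(levels(txf), txid)
    strand <- as.character(GenomicRanges::strand(ex))[fi]
    minus <- strand == "-"
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])

    gmap <- as.character(exmc$gene_id)
    gname <- if (!is.null(exmc$gene_name)) as.character(exmc$gene_name) else gmap
    gname[is.na(gname)] <- gmap[is.na(gname)]
    btype <- as.character(exmc$transcript_type)

    txinfo <- data.frame(
        transcript_id = levels(txf),
        gene_id = gmap[fi],
        gene_name = gname[fi],
        chrom = chrom[fi],
        strand = strand,
        biotype = btype[fi],
        stringsAsFactors = FALSE)

    bare <- GenomicRanges::GRanges(chrom, IRanges::ranges(ex),
                                   strand = GenomicRanges::strand(ex))
    exl <- GenomicRanges::split(bare, txf)
    if (any(minus))
        exl[minus] <- S4Vectors::revElements(exl[minus])
    names(exl) <- txinfo$transcript_id
    txinfo$spliced_length <- unname(sum(GenomicRanges::width(exl)))

    ## CDS -> transcript-coordinate regions
    regions <- DataFrame(transcript_id = character(0), region = character(0),
                         start = integer(0), end = integer(0))
    cds <- gr[types == "CDS"]
    if (length(cds) > 0) {
        cid <- as.character(S4Vectors::mcols(cds)$transcript_id)
        reg <- lapply(intersect(unique(cid), txinfo$transcript_id), function(tid) {
            g <- cds[cid == tid]
            i <- match(tid, txinfo$transcript_id)
            e <- exl[[i]]
            s0 <- GenomicRanges::start(e) - 1L
            e0 <- GenomicRanges::end(e)
            str <- txinfo$strand[i]
            g5 <- if (str == "+") min(GenomicRanges::start(g)) - 1L
                  else max(GenomicRanges::end(g)) - 1L
            t1 <- .genomicToTx(s0, e0, str, g5)
            clen <- sum(GenomicRanges::width(g))
            L <- txinfo$spliced_length[i]
            data.frame(transcript_id = tid,
                       region = c("UTR5", "CDS", "UTR3"),
                       start = c(0L, t1, t1 + clen),
                       end = c(t1, t1 + clen, L))
        })
        if (length(reg) > 0) {
            reg <- do.call(rbind, reg)
            reg <- reg[reg$end > reg$start, , drop = FALSE]
            regions <- DataFrame(reg)
        }
    }

    ## gene-level table (exon-level aggregation, no per-gene S4 work)
    exGene <- gmap
    gstart <- tapply(GenomicRanges::start(ex) - 1L, exGene, min)
    gend <- tapply(GenomicRanges::end(ex), exGene, max)
    gsplit <- split(seq_len(nrow(txinfo)), txinfo$gene_id)
    gids <- names(gsplit)
    strands <- vapply(gsplit, function(i) {
        u <- unique(txinfo$strand[i])
        if (length(u) > 1) NA_character_ else u
    }, character(1))
    if (anyNA(strands))
        .stopf("gene %s has transcripts on both strands",
               gids[which(is.na(strands))[1]])
    genes <- data.frame(
        gene_id = gids,
        gene_name = vapply(gsplit, function(i) txinfo$gene_name[i[1]],
                           character(1)),
        chrom = vapply(gsplit, function(i) txinfo$chrom[i[1]], character(1)),
        strand = unname(strands),
        start = as.integer(gstart[gids]),
        end = as.integer(gend[gids]),
        biotypes = vapply(gsplit, function(i)
            paste(sort(unique(txinfo$biotype[i])), collapse = ","),
            character(1)),
        stringsAsFactors = FALSE)
    genes <- genes[order(genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL

    new("TranscriptModels",
        transcripts = DataFrame(txinfo),
        exons = exl,
        sequences = stats::setNames(seqs, txinfo$transcript_id),
        regions = regions,
        genes = DataFrame(genes))
}

#' Subset models to a set of genes
#'
#' @param models a \linkS4class{TranscriptModels}.
#' @param geneIds gene ids to keep.
#' @return A \linkS4class{TranscriptModels} restricted to those genes,
#'   order preserved (sorted by id).
#' @export
subsetByGenes <- function(models, geneIds) {
    keep <- models@transcripts$gene_id %in% geneIds
    tx <- models@transcripts[keep, , drop = FALSE]
    new("TranscriptModels",
        transcripts = tx,
        exons = models@exons[keep],
        sequences = models@sequences[keep],
        regions = models@regions[
            models@regions$transcript_id %in% tx$transcript_id, , drop = FALSE],
        genes = models@genes[models@genes$gene_id %in% geneIds, , drop = FALSE])
}

#' Construct the lncRNA gene set
#'
#' Keeps genes all of whose transcript biotypes are long-non-coding
#' (\code{antisense}, \code{lincRNA}, \code{non_coding},
#' \code{processed_transcript}), then excludes genes with any
#' pseudogene biotype, genes with any splice isoform shorter than
#' 200 nt, and genes whose symbol matches a supplied coding-gene symbol
#' list (case-insensitive). One exclusion reason is recorded per gene.
#'
#' @param models a \linkS4class{TranscriptModels} with all genes.
#' @param codingSymbols character vector of coding-gene symbols
#'   (may be empty).
#' @param minIsoformLength minimum spliced isoform length in nt
#'   (default 200).
#' @return A list with \code{models} (the retained genes) and
#'   \code{report}, a \linkS4class{LncrnaSetReport} whose intergenic
#'   counts are NA until \code{\link{selectIntergenic}} has run.
#' @export
selectLncrnaGenes <- function(models, codingSymbols = character(0),
                              minIsoformLength = 200L) {
    genes <- models@genes
    tx <- models@transcripts
    codingSymbols <- tolower(codingSymbols)

    txGene <- as.character(tx$gene_id)
    txBiotype <- as.character(tx$biotype)
    txLen <- as.integer(tx$spliced_length)
    geneIds <- as.character(genes$gene_id)
    geneNames <- as.character(genes$gene_name)
    txByGene <- split(seq_along(txGene), txGene)
    reason <- character(nrow(genes))
    for (i in seq_len(nrow(genes))) {
        idx <- txByGene[[geneIds[i]]]
        bt <- unique(txBiotype[idx])
        if (any(grepl("pseudogene", bt))) {
            reason[i] <- "pseudogene"
        } else if (!all(bt %in% LNC_BIOTYPES)) {
            reason[i] <- "non-lnc biotype"
        } else if (any(txLen[idx] < minIsoformLength)) {
            reason[i] <- sprintf("isoform <%d nt", minIsoformLength)
        } else if (tolower(geneNames[i]) %in% codingSymbols) {
            reason[i] <- "coding symbol"
        }
    }
    keep <- reason == ""
    kept <- subsetByGenes(models, geneIds[keep])
    report <- new("LncrnaSetReport",
        nGenesIn = nrow(genes),
        nLncrnaGenes = sum(keep),
        nLncrnaTranscripts = nrow(kept@transcripts),
        nIntergenicGenes = NA_integer_,
        nIntergenicTranscripts = NA_integer_,
        excluded = data.frame(gene_id = genes$gene_id[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
    list(models = kept, report = report)
}

#' Select intergenic lncRNA genes
#'
#' Keeps a lncRNA gene only if its genomic span is separated by at
#' least \code{minSeparation} nucleotides from the span of every other
#' annotated gene on the same chromosome (strand ignored; overlap
#' counts as separation 0).
#'
#' @param lncModels \linkS4class{TranscriptModels} of the lncRNA set.
#' @param allModels \linkS4class{TranscriptModels} of all annotated
#'   genes (coding and non-coding).
#' @param minSeparation minimum gap in nucleotides (default 10000).
#' @return A \linkS4class{TranscriptModels} with the intergenic genes.
#' @export
selectIntergenic <- function(lncModels, allModels, minSeparation = 10000L) {
    lg <- lncModels@genes
    ag <- allModels@genes
    if (nrow(lg) == 0) return(lncModels)
    lgr <- GenomicRanges::GRanges(lg$chrom,
        IRanges::IRanges(lg$start + 1L, lg$end))
    agr <- GenomicRanges::GRanges(ag$chrom,
        IRanges::IRanges(ag$start + 1L, ag$end))
    hits <- GenomicRanges::findOverlaps(lgr, agr,
        maxgap = max(minSeparation - 1L, -1L), ignore.strand = TRUE)
    tooClose <- lg$gene_id[S4Vectors::queryHits(hits)] !=
        ag$gene_id[S4Vectors::subjectHits(hits)]
    bad <- unique(S4Vectors::queryHits(hits)[tooClose])
    subsetByGenes(lncModels, setdiff(lg$gene_id, lg$gene_id[bad]))
}

#' Take the top-scoring genes
#'
#' Selects the \code{topN} genes by descending score; ties are broken
#' by lexicographic gene id. Genes without a score are skipped with a
#' warning.
#'
#' @param models a \linkS4class{TranscriptModels}.
#' @param scores named numeric vector, names are gene ids.
#' @param topN number of genes to keep.
#' @return A \linkS4class{TranscriptModels} with the selected genes.
#' @export
subsetByScore <- function(models, scores, topN) {
    gids <- models@genes$gene_id
    missing <- setdiff(gids, names(scores))
    if (length(missing) > 0)
        warning(length(missing), " gene(s) without a score were skipped")
    scored <- intersect(gids, names(scores))
    if (topN > length(scored))
        .stopf("topN (%d) exceeds the number of scored genes (%d)",
               topN, length(scored))
    s <- scores[scored]
    o <- order(-s, scored)
    subsetByGenes(models, scored[o][seq_len(topN)])
}
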