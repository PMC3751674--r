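#' @include AllClasses.R utils.R
NULL

#' Construct a SeedFamilySet
#'
#' @param family family names (unique).
#' @param seed 7-nt seeds, RNA alphabet (T is accepted and converted
#'   to U).
#' @param conservation_class "conserved" or "nonconserved", recycled.
#' @return A \linkS4class{SeedFamilySet}.
#' @export
seedFamilySet <- function(family, seed, conservation_class = "conserved") {
    df <- DataFrame(family = as.character(family),
                    seed = .dnaToRna(seed),
                    conservation_class = rep(conservation_class,
                                             length.out = length(family)))
    new("SeedFamilySet", families = df)
}

#' Read a seed-family table
#'
#' Expects a TSV with columns \code{family}, \code{seed_7mer},
#' \code{conservation_class}, modelled on TargetScan family
#' definitions.
#'
#' @param path path to the TSV file.
#' @return A \linkS4class{SeedFamilySet}.
#' @export
readSeedFamilies <- function(path) {
    df <- .readTsv(path)
    need <- c("family", "seed_7mer", "conservation_class")
    if (!all(need %in% colnames(df)))
        .stopf("seed table must have columns %s", paste(need, collapse = ", "))
    seedFamilySet(df$family, df$seed_7mer, df$conservation_class)
}

#' Expand a seed into its target-site patterns
#'
#' A microRNA seed (positions 2-8) defines three site types in the
#' target, searched as DNA in the sense transcript sequence:
#' \describe{
#'   \item{7mer-m8}{the reverse complement of the full 7-nt seed;}
#'   \item{8mer}{the 7mer-m8 followed by an A opposite microRNA
#'     position 1;}
#'   \item{7mer-A1}{the reverse complement of seed positions 1-6
#'     (microRNA positions 2-7) followed by an A.}
#' }
#'
#' @param seed a 7-nt seed (RNA or DNA alphabet).
#' @return data.frame with columns \code{site_type}, \code{match_dna}.
#' @examples
#' seedToPatterns("GAGGUAG")  # let-7 family
#' @export
seedToPatterns <- function(seed) {
    seed <- .dnaToRna(seed)
    if (nchar(seed) != 7L || grepl("[^ACGU]", seed))
        .stopf("seed must be a 7-nt string over A/C/G/U, got '%s'", seed)
    m8 <- .revcompDNA(seed)
    data.frame(site_type = SITE_TYPES,
               match_dna = c(paste0(m8, "A"), m8,
                             paste0(.revcompDNA(substr(seed, 1L, 6L)), "A")),
               stringsAsFactors = FALSE)
}

## pattern table for a set of (possibly replicated) seeds:
## columns set_id, family, conservation_class, site_type, match_dna
.patternTable <- function(families, seeds, set_id, conservation_class = NA) {
    n <- length(seeds)
    seeds <- .dnaToRna(seeds)
    if (any(nchar(seeds) != 7L) || any(grepl("[^ACGU]", seeds)))
        .stopf("seeds must be 7-nt strings over A/C/G/U")
    m8 <- .revcompDNA(seeds)
    data.frame(set_id = rep(rep(set_id, length.out = n), 3L),
               family = rep(families, 3L),
               conservation_class = rep(rep(conservation_class,
                                            length.out = n), 3L),
               site_type = rep(SITE_TYPES, each = n),
               match_dna = c(paste0(m8, "A"), m8,
                             paste0(.revcompDNA(substr(seeds, 1L, 6L)), "A")),
               stringsAsFactors = FALSE)
}

## exact scan of a pattern table over a DNAStringSet; returns 0-based
## transcript start positions with the per-locus best-site-type rule
## applied within each (set_id, family):
##   - a 7mer-m8 at the start of an 8mer match is suppressed
##   - a 7mer-A1 one base into an 8mer match is suppressed
.scanPatterns <- function(seqs, patterns) {
    stopifnot(all(nchar(patterns$match_dna) %in% c(7L, 8L)))
    empty <- data.frame(set_id = character(0), family = character(0),
                        conservation_class = character(0),
                        site_type = character(0), seq_idx = integer(0),
                        start = integer(0), width = integer(0),
                        stringsAsFactors = FALSE)
    if (length(seqs) == 0 || nrow(patterns) == 0) return(empty)

    ## single pass over an N-joined concatenation of all transcripts:
    ## patterns are at most 8 nt, so a 10-N spacer cannot be crossed
    spacer <- 10L
    ws <- Biostrings::width(seqs)
    offsets <- cumsum(c(0L, utils::head(ws + spacer, -1L)))
    big <- Biostrings::DNAString(
        paste0(as.character(seqs), collapse = strrep("N", spacer)))
    hitList <- vector("list", 2L)
    for (wi in 1:2) {
        w <- c(8L, 7L)[wi]
        pat <- unique(patterns$match_dna[nchar(patterns$match_dna) == w])
        if (length(pat) == 0) next
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat))
        si <- Biostrings::startIndex(Biostrings::matchPDict(pd, big))
        ns <- lengths(si)
        if (sum(ns) == 0) next
        starts0 <- unlist(si, use.names = FALSE) - 1L
        idx <- findInterval(starts0, offsets)
        hitList[[wi]] <- data.frame(
            match_dna = rep(pat, ns),
            seq_idx = idx,
            start = starts0 - offsets[idx],
            stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, hitList)
    if (is.null(hits) || nrow(hits) == 0) return(empty)

    ## expand to pattern rows (one string can serve several families/sets)
    idxmap <- split(seq_len(nrow(patterns)), patterns$match_dna)
    rows <- idxmap[hits$match_dna]
    nrep <- lengths(rows)
    hits <- hits[rep(seq_len(nrow(hits)), nrep), , drop = FALSE]
    prow <- unlist(rows, use.names = FALSE)
    out <- data.frame(set_id = patterns$set_id[prow],
                      family = patterns$family[prow],
                      conservation_class = patterns$conservation_class[prow],
                      site_type = patterns$site_type[prow],
                      seq_idx = hits$seq_idx,
                      start = hits$start,
                      width = nchar(patterns$match_dna[prow]),
                      stringsAsFactors = FALSE)

    ## per-locus suppression within (set_id, family)
    key <- function(set, fam, seq, pos) paste(set, fam, seq, pos, sep = "\r")
    is8 <- out$site_type == "8mer"
    k8 <- key(out$set_id[is8], out$family[is8], out$seq_idx[is8],
              out$start[is8])
    drop <- logical(nrow(out))
    im8 <- out$site_type == "7mer-m8"
    drop[im8] <- key(out$set_id[im8], out$family[im8], out$seq_idx[im8],
                     out$start[im8]) %in% k8
    ia1 <- out$site_type == "7mer-A1"
    drop[ia1] <- key(out$set_id[ia1], out$family[ia1], out$seq_idx[ia1],
                     out$start[ia1] - 1L) %in% k8
    out <- out[!drop, , drop = FALSE]

    ## a locus keeps its best site type (handles degenerate pattern ties)
    pri <- match(out$site_type, SITE_TYPES)
    o <- order(out$set_id, out$family, out$seq_idx, out$start, pri)
    out <- out[o, , drop = FALSE]
    dup <- duplicated(key(out$set_id, out$family, out$seq_idx, out$start))
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
    out
}

## genomic pieces of transcript-coordinate sites; sites get genome_pos =
## genomic coordinate (0-based) of the 5'-most base in transcript
## orientation; a junction-spanning site yields several pieces. Each
## piece records the expected plus-strand genomic string of the match.
## Pieces are returned as one data.frame keyed by site index.
.siteGenomicPieces <- function(sites, models) {
    tx <- models@transcripts
    exl <- models@exons
    n <- nrow(sites)
    sites$chrom <- tx$chrom[sites$tx_idx]
    sites$strand <- tx$strand[sites$tx_idx]
    sites$genome_pos <- rep(NA_integer_, n)
    ## flatten exon structure once: S4 extraction per transcript is slow
    ust <- unlist(GenomicRanges::start(exl), use.names = FALSE)
    uen <- unlist(GenomicRanges::end(exl), use.names = FALSE)
    nper <- S4Vectors::elementNROWS(exl)
    offs <- cumsum(c(0L, nper))
    seqChars <- as.character(models@sequences)
    acc <- vector("list", 0L)
    for (g in split(seq_len(n), sites$tx_idx)) {
        ti <- sites$tx_idx[g[1]]
        sel <- (offs[ti] + 1L):offs[ti + 1L]
        es <- ust[sel] - 1L
        ee <- uen[sel]
        str <- tx$strand[ti]
        minus <- str == "-"
        txseq <- seqChars[ti]
        cs <- cumsum(c(0L, ee - es))
        p <- sites$start[g]
        q <- p + sites$width[g]
        k1 <- findInterval(p, cs)
        k2 <- findInterval(q - 1L, cs)
        sites$genome_pos[g] <- if (minus) ee[k1] - (p - cs[k1]) - 1L
                               else es[k1] + (p - cs[k1])
        single <- k1 == k2
        if (any(single)) {
            js <- g[single]; ks <- k1[single]
            lo <- p[single]; hi <- q[single]
            gs <- if (minus) ee[ks] - (hi - cs[ks]) else es[ks] + (lo - cs[ks])
            acc[[length(acc) + 1L]] <- data.frame(
                site = js, gs = gs, ge = gs + (hi - lo),
                txpart = substring(txseq, lo + 1L, hi),
                minus = minus, stringsAsFactors = FALSE)
        }
        for (jj in which(!single)) {
            j <- g[jj]
            for (k in k1[jj]:k2[jj]) {
                lo <- max(p[jj], cs[k]); hi <- min(q[jj], cs[k + 1L])
                gs <- if (minus) ee[k] - (hi - cs[k]) else es[k] + (lo - cs[k])
                acc[[length(acc) + 1L]] <- data.frame(
                    site = j, gs = gs, ge = gs + (hi - lo),
                    txpart = substring(txseq, lo + 1L, hi),
                    minus = minus, stringsAsFactors = FALSE)
            }
        }
    }
    pieces <- if (length(acc) > 0) do.call(rbind, acc)
              else data.frame(site = integer(0), gs = integer(0),
                              ge = integer(0), txpart = character(0),
                              minus = logical(0))
    pieces <- pieces[order(pieces$site, pieces$gs), , drop = FALSE]
    pieces$expected <- pieces$txpart
    if (any(pieces$minus))
        pieces$expected[pieces$minus] <- .revcompDNA(pieces$txpart[pieces$minus])
    pieces$txpart <- NULL
    rownames(pieces) <- NULL
    list(sites = sites, pieces = pieces)
}

## region of the site's 5'-most transcript base: UTR5/CDS/UTR3 for
## transcripts with CDS annotation, LNC otherwise
.assignRegions <- function(sites, models) {
    reg <- models@regions
    tx <- models@transcripts
    sites$region <- rep("LNC", nrow(sites))
    if (nrow(reg) == 0 || nrow(sites) == 0) return(sites)
    hasReg <- unique(reg$transcript_id)
    tid <- tx$transcript_id[sites$tx_idx]
    idx <- which(tid %in% hasReg)
    for (j in idx) {
        r <- reg[reg$transcript_id == tid[j], , drop = FALSE]
        p <- sites$start[j]
        hit <- which(p >= r$start & p < r$end)
        sites$region[j] <- if (length(hit) > 0) r$region[hit[1]] else "LNC"
    }
    sites
}

#' Scan transcripts for seed-match target sites
#'
#' Finds all exact occurrences of each family's 8mer, 7mer-m8 and
#' 7mer-A1 patterns in the spliced transcript sequences. Overlapping
#' occurrences are all reported, but each locus is assigned its best
#' site type (8mer > 7mer-m8 > 7mer-A1): the 7mers contained in an
#' 8mer match are suppressed. Transcript positions are mapped to
#' genome coordinates through the exon structure, strand-aware; a site
#' spanning a splice junction is reported at the genomic position of
#' its 5'-most base in transcript orientation.
#'
#' @param models a \linkS4class{TranscriptModels}.
#' @param families a \linkS4class{SeedFamilySet}.
#' @return data.frame of target sites with columns \code{family},
#'   \code{conservation_class}, \code{site_type}, \code{transcript_id},
#'   \code{gene_id}, \code{transcript_pos} (0-based), \code{width},
#'   \code{region}, \code{chrom}, \code{strand}, \code{genome_pos}
#'   (0-based, 5'-most transcript base).
#' @export
scanTranscripts <- function(models, families) {
    fam <- familyTable(families)
    patterns <- .patternTable(fam$family, fam$seed, set_id = "observed",
                              conservation_class = fam$conservation_class)
    sites <- .scanPatterns(models@sequences, patterns)
    .finishSites(sites, models)
}

## shared post-processing: genome mapping + region labels + id columns
.finishSites <- function(sites, models) {
    names(sites)[names(sites) == "seq_idx"] <- "tx_idx"
    mapped <- .siteGenomicPieces(sites, models)
    sites <- mapped$sites
    sites <- .assignRegions(sites, models)
    tx <- models@transcripts
    sites$transcript_id <- tx$transcript_id[sites$tx_idx]
    sites$gene_id <- tx$gene_id[sites$tx_idx]
    names(sites)[names(sites) == "start"] <- "transcript_pos"
    attr(sites, "pieces") <- mapped$pieces
    sites
}

#' Genomic ranges of target sites
#'
#' Expands a site table (from \code{\link{scanTranscripts}}) into a
#' \code{GRanges} with one range per genomic piece (junction-spanning
#' sites yield several pieces carrying the same \code{site} index).
#'
#' @param sites a site table with its piece attribute intact.
#' @return A \code{GRanges} with metadata columns \code{site},
#'   \code{family}, \code{site_type}.
#' @export
siteGenomicRanges <- function(sites) {
    m <- attr(sites, "pieces")
    if (is.null(m)) .stopf("site table has lost its genomic pieces")
    if (nrow(m) == 0)
        return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
        sites$chrom[m$site],
        IRanges::IRanges(start = m$gs + 1L, end = m$ge),
        strand = sites$strand[m$site],
        site = m$site,
        family = sites$family[m$site],
        site_type = sites$site_type[m$site])
}
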