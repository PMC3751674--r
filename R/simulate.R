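#' @include AllClasses.R seeds.R utils.R
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a synthetic dataset configuration
#'
#' Defaults describe a small multi-species study: 13 species in three
#' clades around a primate reference, 87 conserved + 87 non-conserved
#' seed families, human-like background GC (0.41), clade divergence
#' rising from primates to non-mammal vertebrates, and fraction counts
#' from seven cell lines with negative binomial noise (dispersion
#' 0.1). \code{plantedEnrichment} sets the target observed/expected
#' factor for conserved 8mer sites at \code{plantedSiteTier}; 1 means
#' nothing is planted.
#'
#' @param seedRng integer RNG seed.
#' @param nSpeciesPerClade named counts (primate, mammal, vertebrate).
#' @param nCodingGenes,nLncrnaGenes gene counts.
#' @param utr5Len,utr3Len,cdsLen,lncLen region lengths (nt).
#' @param backgroundGc background GC fraction.
#' @param cladeDivergence per-site substitution probability per clade,
#'   non-decreasing primate -> vertebrate.
#' @param plantedEnrichment target observed/expected factor (>= 0).
#' @param plantedSiteTier clade tier of the planted sites.
#' @param nSeedFamiliesConserved,nSeedFamiliesNonconserved family counts.
#' @param cytoBiasFraction fraction of lncRNAs that are cytoplasmic.
#' @param minFraction clade intact-fraction threshold assumed when
#'   sizing the planted-site count.
#' @param intergenicGap gap between adjacent gene loci (nt).
#' @param cellLines cell line names.
#' @param meanDepth mean per-gene reads per library.
#' @param fracBias cytoplasm:nucleus fold bias for cytoplasmic genes.
#' @param lowExprFraction fraction of genes at near-zero expression.
#' @param nbDispersion negative binomial dispersion.
#' @param twoExonFraction fraction of lncRNAs with two exons.
#' @param includeDecoys emit decoy genes exercising each filter rule.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(seedRng = 1L,
                      nSpeciesPerClade = c(primate = 4L, mammal = 5L,
                                           vertebrate = 4L),
                      nCodingGenes = 20L, nLncrnaGenes = 100L,
                      utr5Len = 200L, utr3Len = 800L, cdsLen = 900L,
                      lncLen = 800L,
                      backgroundGc = 0.41,
                      cladeDivergence = c(primate = 0.02, mammal = 0.08,
                                          vertebrate = 0.30),
                      plantedEnrichment = 1,
                      plantedSiteTier = "mammal",
                      nSeedFamiliesConserved = 87L,
                      nSeedFamiliesNonconserved = 87L,
                      cytoBiasFraction = 0.3,
                      minFraction = 0.5,
                      intergenicGap = 12000L,
                      cellLines = c("GM12878", "HelaS3", "HepG2", "HUVEC",
                                    "H1hESC", "NHEK", "K562"),
                      meanDepth = 100, fracBias = 4,
                      lowExprFraction = 0.1,
                      nbDispersion = 0.1, twoExonFraction = 0.2,
                      includeDecoys = TRUE) {
    nsp <- as.integer(nSpeciesPerClade)
    names(nsp) <- names(nSpeciesPerClade)
    new("SimConfig",
        seedRng = as.integer(seedRng),
        nSpeciesPerClade = nsp[CLADE_LEVELS],
        nCodingGenes = as.integer(nCodingGenes),
        nLncrnaGenes = as.integer(nLncrnaGenes),
        utr5Len = as.integer(utr5Len), utr3Len = as.integer(utr3Len),
        cdsLen = as.integer(cdsLen), lncLen = as.integer(lncLen),
        backgroundGc = backgroundGc,
        cladeDivergence = cladeDivergence[CLADE_LEVELS],
        plantedEnrichment = plantedEnrichment,
        plantedSiteTier = plantedSiteTier,
        nSeedFamiliesConserved = as.integer(nSeedFamiliesConserved),
        nSeedFamiliesNonconserved = as.integer(nSeedFamiliesNonconserved),
        cytoBiasFraction = cytoBiasFraction,
        minFraction = minFraction,
        intergenicGap = as.integer(intergenicGap),
        cellLines = cellLines,
        meanDepth = meanDepth, fracBias = fracBias,
        lowExprFraction = lowExprFraction,
        nbDispersion = nbDispersion,
        twoExonFraction = twoExonFraction,
        includeDecoys = includeDecoys)
}

.randomBases <- function(n, gc) {
    sample(DNA_BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.uniqueSeeds <- function(n, avoid = character(0)) {
    out <- character(0)
    while (length(out) < n) {
        batch <- vapply(seq_len(n), function(i)
            paste0(sample(RNA_ALPHABET, 7L, replace = TRUE), collapse = ""),
            character(1))
        out <- unique(c(out, setdiff(batch, avoid)))
    }
    out[seq_len(n)]
}

## expected number of background 8mer matches, for the given patterns,
## that land in the cumulative stratum of `tier`, under iid base
## frequencies `freq` (DNA, named) and the clade substitution model
.analyticExpectedCount <- function(patterns8, txLens, freq, nspPerClade,
                                   divergence, tier, minFraction) {
    positions <- sum(pmax(txLens - 7L, 0L))
    pmatch <- vapply(strsplit(patterns8, "", fixed = TRUE),
                     function(ch) prod(freq[ch]), numeric(1))
    groups <- c(primate = unname(nspPerClade["primate"]) - 1L,
                mammal = unname(nspPerClade["mammal"]),
                vertebrate = unname(nspPerClade["vertebrate"]))
    q <- (1 - divergence)^8
    pcons <- 1
    for (cl in CLADE_LEVELS[seq_len(match(tier, CLADE_LEVELS))]) {
        ng <- groups[[cl]]
        if (ng == 0) next
        k <- ceiling(minFraction * ng)
        pcons <- pcons * (1 - stats::pbinom(k - 1, ng, q[[cl]]))
    }
    positions * sum(pmatch) * pcons
}

## substitute each position independently with probability d; the new
## base is uniform over the three others
.mutateChars <- function(chars, d) {
    if (d <= 0) return(chars)
    idx <- which(stats::runif(length(chars)) < d)
    if (length(idx) == 0) return(chars)
    cur <- match(chars[idx], DNA_BASES)
    off <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- DNA_BASES[(cur - 1L + off) %% 4L + 1L]
    chars
}

#' Generate a complete synthetic dataset
#'
#' Emits every input of the analysis pipeline into \code{outDir}:
#' \code{genome.fa} (reference species), \code{alignment.maf} (one
#' block per gene locus, all species), \code{annotation.gtf}
#' (GENCODE-dialect attributes), \code{seeds.tsv}, \code{clades.tsv},
#' \code{counts.tsv}, \code{coding_symbols.txt}, plus audit files
#' \code{planted_sites.tsv} and \code{cytoplasmic_genes.txt}.
#'
#' Conserved-family 8mer sites are planted into the clean intergenic
#' lncRNA transcripts so that the expected observed/expected ratio at
#' the planted stratum equals \code{plantedEnrichment}: the number of
#' extra sites is \code{round((e - 1) * E)} where E is the analytic
#' expected count of clade-conserved background matches under the
#' emitted composition. Planted sites are held invariant in all
#' species of the planted tier's clades and carry at least two seed
#' mismatches in deeper clades. With \code{plantedEnrichment = 1}
#' nothing is planted.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outDir output directory (created if needed).
#' @return A \linkS4class{GroundTruth}.
#' @export
generateDataset <- function(config, outDir) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    set.seed(config@seedRng)

    ## ---- species and clades ----
    nsp <- config@nSpeciesPerClade
    species <- unlist(lapply(CLADE_LEVELS, function(cl)
        sprintf("%s%d", cl, seq_len(nsp[[cl]]))))
    spClade <- rep(CLADE_LEVELS, nsp)
    refSpecies <- species[1]

    ## ---- seed families ----
    nc <- config@nSeedFamiliesConserved
    nn <- config@nSeedFamiliesNonconserved
    seeds <- .uniqueSeeds(nc + nn)
    famTab <- data.frame(
        family = c(sprintf("fam-C%03d", seq_len(nc)),
                   sprintf("fam-N%03d", seq_len(nn))),
        seed_7mer = seeds,
        conservation_class = rep(c("conserved", "nonconserved"), c(nc, nn)),
        stringsAsFactors = FALSE)

    ## ---- gene plan ----
    intron <- 150L
    mkCoding <- function(i) {
        L <- config@utr5Len + config@cdsLen + config@utr3Len
        cuts <- sort(sample(seq(60L, L - 60L), 2L))
        exLens <- c(cuts[1], cuts[2] - cuts[1], L - cuts[2])
        list(gene_id = sprintf("CODG%04d", i),
             gene_name = sprintf("CGENE%d", i),
             gene_type = "protein_coding",
             tx = list(list(transcript_id = sprintf("CODT%04d", i),
                            transcript_type = "protein_coding",
                            exLens = exLens, coding = TRUE)),
             clean_lnc = FALSE)
    }
    mkLnc <- function(i) {
        two <- stats::runif(1) < config@twoExonFraction
        exLens <- if (two) {
            a <- sample(seq(60L, config@lncLen - 60L), 1L)
            c(a, config@lncLen - a)
        } else config@lncLen
        list(gene_id = sprintf("LNCG%04d", i),
             gene_name = sprintf("LNC%d", i),
             gene_type = "lincRNA",
             tx = list(list(transcript_id = sprintf("LNCT%04d", i),
                            transcript_type = "lincRNA",
                            exLens = exLens, coding = FALSE)),
             clean_lnc = TRUE)
    }
    genes <- c(lapply(seq_len(config@nCodingGenes), mkCoding),
               lapply(seq_len(config@nLncrnaGenes), mkLnc))
    if (config@includeDecoys) {
        dec <- list(
            list(gene_id = "DECG0001", gene_name = "DECPSEUDO",
                 gene_type = "processed_pseudogene",
                 tx = list(list(transcript_id = "DECT0001",
                                transcript_type = "processed_pseudogene",
                                exLens = 400L, coding = FALSE)),
                 clean_lnc = FALSE),
            list(gene_id = "DECG0002", gene_name = "DECSHORT",
                 gene_type = "lincRNA",
                 tx = list(list(transcript_id = "DECT0002a",
                                transcript_type = "lincRNA",
                                exLens = config@lncLen, coding = FALSE),
                           list(transcript_id = "DECT0002b",
                                transcript_type = "lincRNA",
                                exLens = 150L, coding = FALSE)),
                 clean_lnc = FALSE),
            list(gene_id = "DECG0003", gene_name = "DECMIXED",
                 gene_type = "lincRNA",
                 tx = list(list(transcript_id = "DECT0003a",
                                transcript_type = "lincRNA",
                                exLens = config@lncLen, coding = FALSE),
                           list(transcript_id = "DECT0003b",
                                transcript_type = "protein_coding",
                                exLens = 300L, coding = FALSE)),
                 clean_lnc = FALSE),
            list(gene_id = "DECG0004", gene_name = "TP53",
                 gene_type = "lincRNA",
                 tx = list(list(transcript_id = "DECT0004",
                                transcript_type = "lincRNA",
                                exLens = config@lncLen, coding = FALSE)),
                 clean_lnc = FALSE),
            list(gene_id = "DECG0005", gene_name = "DECCLOSEA",
                 gene_type = "lincRNA", close_pair = TRUE,
                 tx = list(list(transcript_id = "DECT0005",
                                transcript_type = "lincRNA",
                                exLens = config@lncLen, coding = FALSE)),
                 clean_lnc = FALSE),
            list(gene_id = "DECG0006", gene_name = "DECCLOSEB",
                 gene_type = "lincRNA", close_pair = TRUE,
                 tx = list(list(transcript_id = "DECT0006",
                                transcript_type = "lincRNA",
                                exLens = config@lncLen, coding = FALSE)),
                 clean_lnc = FALSE))
        genes <- c(genes, dec)
    }

    ## per-gene structure: exon local intervals (genomic order, 0-based
    ## half-open within the locus), strand, locus length
    for (i in seq_along(genes)) {
        g <- genes[[i]]
        g$strand <- sample(c("+", "-"), 1L)
        for (j in seq_along(g$tx)) {
            exLens <- g$tx[[j]]$exLens
            starts <- cumsum(c(0L, head(exLens, -1L) + intron))
            g$tx[[j]]$locStart <- starts
            g$tx[[j]]$locEnd <- starts + exLens
            g$tx[[j]]$splicedLen <- sum(exLens)
        }
        g$locusLen <- max(vapply(g$tx, function(t) max(t$locEnd), integer(1)))
        genes[[i]] <- g
    }

    ## ---- placement on chr1 ----
    unitIdx <- which(!vapply(genes, function(g) isTRUE(g$close_pair),
                             logical(1)))
    pairIdx <- setdiff(seq_along(genes), unitIdx)
    units <- c(as.list(unitIdx),
               if (length(pairIdx) > 0) list(pairIdx))
    units <- units[sample.int(length(units))]
    cursor <- 2000L
    for (u in units) {
        for (k in seq_along(u)) {
            genes[[u[k]]]$locusStart <- cursor
            gap <- if (k < length(u)) 3000L else config@intergenicGap
            cursor <- cursor + genes[[u[k]]]$locusLen + gap
        }
    }
    chromLen <- cursor + 2000L
    chrom <- "chr1"

    ## ---- reference sequence per locus ----
    for (i in seq_along(genes))
        genes[[i]]$refChars <- .randomBases(genes[[i]]$locusLen,
                                            config@backgroundGc)

    ## spliced transcript sequence from locus chars
    spliceTx <- function(g, t) {
        parts <- vapply(seq_along(t$locStart), function(k)
            paste0(g$refChars[(t$locStart[k] + 1L):t$locEnd[k]],
                   collapse = ""), character(1))
        s <- paste0(parts, collapse = "")
        if (g$strand == "-") .revcompDNA(s) else s
    }

    ## ---- analytic expected count and planting ----
    cleanIdx <- which(vapply(genes, function(g) g$clean_lnc, logical(1)))
    cleanLens <- vapply(genes[cleanIdx],
                        function(g) g$tx[[1]]$splicedLen, integer(1))
    cleanSeqs <- vapply(genes[cleanIdx],
                        function(g) spliceTx(g, g$tx[[1]]), character(1))
    freq <- table(factor(strsplit(paste0(cleanSeqs, collapse = ""),
                                  "")[[1]], levels = DNA_BASES))
    freq <- as.numeric(freq) / sum(freq)
    names(freq) <- DNA_BASES
    consSeeds <- famTab$seed_7mer[famTab$conservation_class == "conserved"]
    patterns8 <- vapply(consSeeds,
                        function(s) paste0(.revcompDNA(s), "A"), character(1))
    E <- .analyticExpectedCount(patterns8, cleanLens, freq, nsp,
                                config@cladeDivergence,
                                config@plantedSiteTier, config@minFraction)
    nPlant <- max(0L, round((config@plantedEnrichment - 1) * E))

    planted <- data.frame(gene_id = character(0), transcript_id = character(0),
                          transcript_pos = integer(0), family = character(0),
                          tier = character(0), stringsAsFactors = FALSE)
    plantedLoci <- list()  # per clean gene: locus intervals + patterns
    if (nPlant > 0) {
        if (all(cleanLens < 8L))
            .stopf("transcripts too short to host a site (max spliced length %d < 8)",
                   max(cleanLens))
        if (nPlant * 16 > sum(cleanLens))
            .stopf("impossible enrichment: %d planted sites exceed sequence capacity",
                   nPlant)
        occupied <- lapply(cleanLens, function(L) logical(L))
        wts <- pmax(cleanLens - 7L, 0L)
        famPick <- sample(consSeeds, nPlant, replace = TRUE)
        fails <- 0L
        for (i in seq_len(nPlant)) {
            repeat {
                ci <- sample.int(length(cleanIdx), 1L, prob = wts)
                g <- genes[[cleanIdx[ci]]]
                t <- g$tx[[1]]
                ## exon tx ranges in transcript orientation
                exLens <- t$locEnd - t$locStart
                if (g$strand == "-") exLens <- rev(exLens)
                txStarts <- cumsum(c(0L, head(exLens, -1L)))
                ok <- which(exLens >= 8L)
                if (length(ok) == 0 || fails > 10000L)
                    .stopf("impossible enrichment: could not place planted site %d", i)
                k <- if (length(ok) == 1L) ok else sample(ok, 1L)
                p <- txStarts[k] + sample.int(exLens[k] - 7L, 1L) - 1L
                if (any(occupied[[ci]][(p + 1L):(p + 8L)])) {
                    fails <- fails + 1L
                    next
                }
                occupied[[ci]][(p + 1L):(p + 8L)] <- TRUE
                pat <- paste0(.revcompDNA(famPick[i]), "A")
                ## locus-coordinate interval of the site (single exon)
                exOrd <- if (g$strand == "-") rev(seq_along(t$locStart))
                         else seq_along(t$locStart)
                ke <- exOrd[k]
                off <- p - txStarts[k]
                if (g$strand == "+") {
                    g1 <- t$locStart[ke] + off
                    gpat <- pat
                } else {
                    g1 <- t$locEnd[ke] - off - 8L
                    gpat <- .revcompDNA(pat)
                }
                gi <- cleanIdx[ci]
                genes[[gi]]$refChars[(g1 + 1L):(g1 + 8L)] <-
                    strsplit(gpat, "")[[1]]
                key <- as.character(gi)
                plantedLoci[[key]] <- rbind(plantedLoci[[key]],
                                            data.frame(g1 = g1,
                                                       strand = g$strand))
                fam <- famTab$family[match(famPick[i], famTab$seed_7mer)]
                planted <- rbind(planted, data.frame(
                    gene_id = g$gene_id, transcript_id = t$transcript_id,
                    transcript_pos = p, family = fam,
                    tier = config@plantedSiteTier, stringsAsFactors = FALSE))
                break
            }
        }
    }

    ## ---- species rows and MAF ----
    plantedRank <- match(config@plantedSiteTier, CLADE_LEVELS)
    spRank <- match(spClade, CLADE_LEVELS)
    div <- config@cladeDivergence[spClade]
    order_ <- order(vapply(genes, function(g) g$locusStart, integer(1)))
    mafCon <- file.path(outDir, "alignment.maf")
    mafLines <- vector("list", length(genes))
    for (oi in seq_along(order_)) {
        gi <- order_[oi]
        g <- genes[[gi]]
        refSeq <- paste0(g$refChars, collapse = "")
        rows <- character(length(species))
        rows[1] <- refSeq
        ploci <- plantedLoci[[as.character(gi)]]
        for (s in 2:length(species)) {
            ch <- .mutateChars(g$refChars, div[s])
            if (!is.null(ploci)) {
                for (r in seq_len(nrow(ploci))) {
                    g1 <- ploci$g1[r]
                    sel <- (g1 + 1L):(g1 + 8L)
                    if (spRank[s] <= plantedRank) {
                        ch[sel] <- g$refChars[sel]
                    } else {
                        ## >=2 mismatches within the 7 seed-pairing
                        ## positions (the non-A1 positions of the 8mer)
                        seedSel <- if (ploci$strand[r] == "+")
                            sel[1:7] else sel[2:8]
                        mm <- sum(ch[seedSel] != g$refChars[seedSel])
                        while (mm < 2L) {
                            j <- sample(seedSel, 1L)
                            if (ch[j] == g$refChars[j]) {
                                others <- setdiff(DNA_BASES, g$refChars[j])
                                ch[j] <- sample(others, 1L)
                                mm <- mm + 1L
                            }
                        }
                    }
                }
            }
            rows[s] <- paste0(ch, collapse = "")
        }
        mafLines[[oi]] <- c("a score=0",
            sprintf("s %s.%s %d %d + %d %s", species, chrom, g$locusStart,
                    g$locusLen, chromLen, rows), "")
    }
    writeLines(c("##maf version=1", "", unlist(mafLines)), mafCon)

    ## ---- genome FASTA ----
    pieces <- character(2L * length(genes) + 1L)
    pos <- 0L
    pi_ <- 1L
    for (gi in order_) {
        g <- genes[[gi]]
        pieces[pi_] <- strrep("N", g$locusStart - pos)
        pieces[pi_ + 1L] <- paste0(g$refChars, collapse = "")
        pos <- g$locusStart + g$locusLen
        pi_ <- pi_ + 2L
    }
    pieces[pi_] <- strrep("N", chromLen - pos)
    genome <- Biostrings::DNAStringSet(paste0(pieces, collapse = ""))
    names(genome) <- chrom
    Biostrings::writeXStringSet(genome, file.path(outDir, "genome.fa"),
                                width = 60L)

    ## ---- GTF ----
    attrStr <- function(gid, gname, gtype, tid = NULL, ttype = NULL) {
        s <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
                     gid, gtype, gname)
        if (!is.null(tid))
            s <- paste0(s, sprintf(' transcript_id "%s"; transcript_type "%s";',
                                   tid, ttype))
        s
    }
    gtf <- character(0)
    for (gi in order_) {
        g <- genes[[gi]]
        gs <- g$locusStart
        gtf <- c(gtf, sprintf("%s\tlncmir_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              chrom, gs + 1L, gs + g$locusLen, g$strand,
                              attrStr(g$gene_id, g$gene_name, g$gene_type)))
        for (t in g$tx) {
            a <- attrStr(g$gene_id, g$gene_name, g$gene_type,
                         t$transcript_id, t$transcript_type)
            gtf <- c(gtf, sprintf(
                "%s\tlncmir_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                chrom, gs + min(t$locStart) + 1L, gs + max(t$locEnd),
                g$strand, a))
            for (k in seq_along(t$locStart))
                gtf <- c(gtf, sprintf(
                    "%s\tlncmir_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
                    chrom, gs + t$locStart[k] + 1L, gs + t$locEnd[k],
                    g$strand, a))
            if (isTRUE(t$coding)) {
                ## CDS occupies transcript interval [utr5, utr5+cds)
                cdsTx <- c(config@utr5Len, config@utr5Len + config@cdsLen)
                exLens <- t$locEnd - t$locStart
                exOrd <- if (g$strand == "-") rev(seq_along(exLens))
                         else seq_along(exLens)
                txStarts <- cumsum(c(0L, head(exLens[exOrd], -1L)))
                for (k in seq_along(exOrd)) {
                    lo <- max(cdsTx[1], txStarts[k])
                    hi <- min(cdsTx[2], txStarts[k] + exLens[exOrd[k]])
                    if (lo >= hi) next
                    ke <- exOrd[k]
                    if (g$strand == "+") {
                        c1 <- t$locStart[ke] + (lo - txStarts[k])
                        c2 <- t$locStart[ke] + (hi - txStarts[k])
                    } else {
                        c2 <- t$locEnd[ke] - (lo - txStarts[k])
                        c1 <- t$locEnd[ke] - (hi - txStarts[k])
                    }
                    gtf <- c(gtf, sprintf(
                        "%s\tlncmir_sim\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                        chrom, gs + c1 + 1L, gs + c2, g$strand, a))
                }
            }
        }
    }
    writeLines(gtf, file.path(outDir, "annotation.gtf"))

    ## ---- tables ----
    .writeTsv(famTab, file.path(outDir, "seeds.tsv"))
    .writeTsv(data.frame(species = species, clade = spClade),
              file.path(outDir, "clades.tsv"))
    writeLines(c("TP53", "MYC", "GAPDH"),
               file.path(outDir, "coding_symbols.txt"))

    ## ---- counts ----
    allGeneIds <- vapply(genes[order_], function(g) g$gene_id, character(1))
    cleanGeneIds <- vapply(genes[cleanIdx], function(g) g$gene_id,
                           character(1))
    nCyto <- round(config@cytoBiasFraction * length(cleanGeneIds))
    trueCyto <- sort(sample(cleanGeneIds, nCyto))
    truth <- new("GroundTruth",
                 plantedSites = planted,
                 trueCytoplasmicGenes = trueCyto,
                 analysisGenes = sort(cleanGeneIds),
                 expectedBackgroundCount = E)
    counts <- generateCounts(allGeneIds, truth, config)
    .writeTsv(cbind(data.frame(gene_id = rownames(counts)),
                    as.data.frame(counts)),
              file.path(outDir, "counts.tsv"))

    ## ---- audit files ----
    .writeTsv(planted, file.path(outDir, "planted_sites.tsv"))
    writeLines(trueCyto, file.path(outDir, "cytoplasmic_genes.txt"))
    truth
}

#' Simulate a nuclear/cytoplasmic fraction count matrix
#'
#' Negative binomial counts per gene and library
#' (cell line x fraction). Genes in the ground truth's cytoplasmic
#' set get a cytoplasm:nucleus expected ratio of
#' \code{fracBias}:1 (default 4:1); all other genes get the inverse.
#' A \code{lowExprFraction} of genes is simulated at near-zero
#' expression to exercise the minimum-read filter downstream.
#'
#' @param geneIds character vector of gene ids.
#' @param truth a \linkS4class{GroundTruth} (its
#'   \code{trueCytoplasmicGenes} defines the biased set).
#' @param config a \linkS4class{SimConfig}.
#' @return Integer matrix, genes x libraries, with
#'   \code{<cellline>_<fraction>} column names.
#' @export
generateCounts <- function(geneIds, truth, config) {
    nlib <- 2L * length(config@cellLines)
    libs <- as.vector(rbind(paste0(config@cellLines, "_cytoplasm"),
                            paste0(config@cellLines, "_nucleus")))
    isCyto <- geneIds %in% trueCytoplasmicGenes(truth)
    w <- config@fracBias / (config@fracBias + 1)
    mu <- rep(config@meanDepth, length(geneIds))
    nLow <- round(config@lowExprFraction * length(geneIds))
    if (nLow > 0)
        mu[sample.int(length(geneIds), nLow)] <- 0.005 * config@meanDepth
    m <- matrix(0L, nrow = length(geneIds), ncol = nlib,
                dimnames = list(geneIds, libs))
    for (j in seq_len(nlib)) {
        cytLib <- grepl("_cytoplasm$", libs[j])
        frac <- ifelse(isCyto == cytLib, w, 1 - w)
        mval <- mu * frac
        m[, j] <- stats::rnbinom(length(geneIds), mu = mval,
                                 size = 1 / config@nbDispersion)
    }
    m
}
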