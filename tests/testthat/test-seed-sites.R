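test_that("seed expansion follows the 8mer/7mer-m8/7mer-A1 conventions", {
    p <- seedToPatterns("GAGGUAG")  # let-7 family seed
    expect_equal(p$match_dna[p$site_type == "7mer-m8"], "CTACCTC")
    expect_equal(p$match_dna[p$site_type == "8mer"], "CTACCTCA")
    expect_equal(p$match_dna[p$site_type == "7mer-A1"], "TACCTCA")

    p2 <- seedToPatterns("AAAAAAA")
    expect_equal(sort(p2$match_dna),
                 sort(c("TTTTTTTA", "TTTTTTT", "TTTTTTA")))

    # by construction every 8mer and 7mer-A1 ends in A
    for (s in randomRnaSeeds(25, seed = 3)) {
        p <- seedToPatterns(s)
        expect_equal(nrow(p), 3L)
        expect_match(p$match_dna[p$site_type == "8mer"], "A$")
        expect_match(p$match_dna[p$site_type == "7mer-A1"], "A$")
        expect_equal(p$match_dna[p$site_type == "8mer"],
                     paste0(p$match_dna[p$site_type == "7mer-m8"], "A"))
    }
    expect_error(seedToPatterns("GAGGTXG"), "A/C/G/U")
    expect_error(seedToPatterns("GAGGUA"), "7-nt")
})

test_that("scanning finds sites and assigns the best type per locus", {
    tx <- list(list(transcript_id = "T1", gene_id = "G1",
                    biotype = "lincRNA", strand = "+",
                    exons = list(c(1, 12))))
    models <- toyModels("AACTACCTCAGG", tx)
    fams <- seedFamilySet("let-7", "GAGGUAG")
    sites <- scanTranscripts(models, fams)
    expect_equal(nrow(sites), 1L)
    expect_equal(sites$site_type, "8mer")
    expect_equal(sites$transcript_pos, 2L)
    expect_equal(sites$region, "LNC")

    models2 <- toyModels("CTACCTCG", list(list(
        transcript_id = "T1", gene_id = "G1", biotype = "lincRNA",
        strand = "+", exons = list(c(1, 8)))))
    sites2 <- scanTranscripts(models2, fams)
    expect_equal(nrow(sites2), 1L)
    expect_equal(sites2$site_type, "7mer-m8")
    expect_equal(sites2$transcript_pos, 0L)

    models3 <- toyModels("GGGGGGGGGGGGGGGGGGGG", list(list(
        transcript_id = "T1", gene_id = "G1", biotype = "lincRNA",
        strand = "+", exons = list(c(1, 20)))))
    expect_equal(nrow(scanTranscripts(models3, fams)), 0L)
})

test_that("scanner agrees with a brute-force position-by-position oracle", {
    seeds <- randomRnaSeeds(5, seed = 11)
    famTab <- data.frame(family = paste0("f", 1:5), seed = seeds)
    seqs <- randomDnaSeqs(200, 60, seed = 12)
    tx <- lapply(seq_along(seqs), function(i)
        list(transcript_id = sprintf("T%03d", i),
             gene_id = sprintf("G%03d", i), biotype = "lincRNA",
             strand = "+", exons = list(c((i - 1) * 70 + 1,
                                          (i - 1) * 70 + 60))))
    genome <- paste0(vapply(seqs, function(s)
        paste0(s, strrep("G", 10)), character(1)), collapse = "")
    models <- toyModels(genome, tx)
    fams <- seedFamilySet(famTab$family, famTab$seed)

    got <- scanTranscripts(models, fams)
    got <- got[order(got$family, got$tx_idx, got$transcript_pos),
               c("family", "tx_idx", "transcript_pos", "site_type")]
    want <- oracleScan(seqs, famTab)
    expect_equal(got$family, want$family)
    expect_equal(got$tx_idx, want$seq_idx)
    expect_equal(got$transcript_pos, want$start)
    expect_equal(got$site_type, want$site_type)

    # no double counting: one site per (family, transcript, locus)
    expect_false(any(duplicated(
        paste(got$family, got$tx_idx, got$transcript_pos))))
})

test_that("minus-strand scanning equals scanning the reverse complement", {
    seqs <- randomDnaSeqs(20, 80, seed = 21)
    rc <- oracleRevcomp(seqs)
    txPlus <- lapply(seq_along(seqs), function(i)
        list(transcript_id = sprintf("P%02d", i), gene_id = sprintf("GP%02d", i),
             biotype = "lincRNA", strand = "+",
             exons = list(c((i - 1) * 90 + 1, (i - 1) * 90 + 80))))
    txMinus <- lapply(seq_along(seqs), function(i)
        list(transcript_id = sprintf("P%02d", i), gene_id = sprintf("GP%02d", i),
             biotype = "lincRNA", strand = "-",
             exons = list(c((i - 1) * 90 + 1, (i - 1) * 90 + 80))))
    genomePlus <- paste0(vapply(seqs, function(s) paste0(s, strrep("G", 10)),
                                character(1)), collapse = "")
    genomeMinus <- paste0(vapply(rc, function(s) paste0(s, strrep("G", 10)),
                                 character(1)), collapse = "")
    fams <- seedFamilySet(paste0("f", 1:4), randomRnaSeeds(4, seed = 22))
    sPlus <- scanTranscripts(toyModels(genomePlus, txPlus), fams)
    sMinus <- scanTranscripts(toyModels(genomeMinus, txMinus), fams)
    key <- function(s) sort(paste(s$family, s$transcript_id,
                                  s$transcript_pos, s$site_type))
    expect_equal(key(sPlus), key(sMinus))
})

test_that("sites map back to genome coordinates through exon structures", {
    # two-exon minus-strand transcript whose let-7 8mer spans the
    # splice junction: spliced tx = AAAAAAAAAACTAC | CTCAGGGGGGGGGG
    e1 <- "GTAGTTTTTTTTTT"   # genomic [26,39]; revcomp = tx piece 1
    e2 <- "CCCCCCCCCCTGAG"   # genomic [6,19];  revcomp = tx piece 2
    genome <- paste0("NNNNN", e2, strrep("N", 6), e1, "NNNNN")
    tx <- list(list(transcript_id = "T1", gene_id = "G1",
                    biotype = "lincRNA", strand = "-",
                    exons = list(c(6, 19), c(26, 39))))
    models <- toyModels(genome, tx)
    txSeq <- as.character(splicedSeqs(models))
    expect_equal(unname(substr(txSeq, 11, 18)), "CTACCTCA")
    fams <- seedFamilySet("let-7", "GAGGUAG")
    sites <- scanTranscripts(models, fams)
    s8 <- sites[sites$site_type == "8mer", ]
    expect_equal(nrow(s8), 1L)
    expect_equal(s8$transcript_pos, 10L)
    expect_equal(s8$strand, "-")
    # 5'-most transcript base maps inside the exon at [26,39] (1-based)
    expect_equal(s8$genome_pos, 28L)  # 0-based: (39) - 1 - 10

    # the genomic pieces reverse-complement back to the match string
    gr <- siteGenomicRanges(sites)
    pg <- gr[gr$site == which(sites$site_type == "8mer")]
    got <- vapply(seq_along(pg), function(i)
        substr(genome, GenomicRanges::start(pg)[i],
               GenomicRanges::end(pg)[i]), character(1))
    # pieces are plus-strand genomic; stitch in transcript orientation
    stitched <- oracleRevcomp(paste0(got[order(GenomicRanges::start(pg))],
                                     collapse = ""))
    expect_equal(stitched, "CTACCTCA")
})

test_that("region assignment uses the 5'-most base and CDS boundaries", {
    # coding transcript: UTR5 = [0,10), CDS = [10,31), UTR3 = [31,60)
    cdsSeq <- "ATGCTACCTCAGGGGGGGTAA"  # 21 nt, contains let-7 8mer at CDS+3
    genome <- paste0("NNNNN", "GGGGGGGGGG", cdsSeq,
                     "CCCCCCTACCTCACCCCCCCCCCCCCCCC", "NNNNN")
    tx <- list(list(transcript_id = "T1", gene_id = "G1",
                    biotype = "protein_coding", strand = "+",
                    exons = list(c(6, 65)), cds = c(16, 36)))
    models <- toyModels(genome, tx)
    reg <- as.data.frame(regionTable(models))
    expect_equal(reg$region, c("UTR5", "CDS", "UTR3"))
    expect_equal(reg$start, c(0L, 10L, 31L))
    expect_equal(reg$end, c(10L, 31L, 60L))

    sites <- scanTranscripts(models, seedFamilySet("let-7", "GAGGUAG"))
    s8 <- sites[sites$site_type == "8mer", ]
    expect_equal(sort(s8$region), c("CDS", "UTR3"))
})
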