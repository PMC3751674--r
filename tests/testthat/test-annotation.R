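test_that("GTF parsing extracts strand-aware spliced sequences", {
    genome <- paste0("GGGGGGGGGG", "AACG", "TTTTTT",
                     "ACGT", "CCCCCC", "AAGGTT", "GG")
    # plus-strand 1-exon over [11,14] -> "AACG"
    # minus-strand 1-exon over [11,14] -> revcomp("AACG") = "CGTT"
    # plus-strand 2-exon [21,24] + [31,36] -> "ACGT" + "AAGGTT", length 10
    tx <- list(
        list(transcript_id = "TP", gene_id = "GP", biotype = "lincRNA",
             strand = "+", exons = list(c(11, 14))),
        list(transcript_id = "TM", gene_id = "GM", biotype = "lincRNA",
             strand = "-", exons = list(c(11, 14))),
        list(transcript_id = "T2", gene_id = "G2", biotype = "lincRNA",
             strand = "+", exons = list(c(21, 24), c(31, 36))))
    models <- toyModels(genome, tx)
    seqs <- as.character(splicedSeqs(models))
    txt <- as.data.frame(transcriptTable(models))
    expect_equal(unname(seqs[txt$transcript_id == "TP"]), "AACG")
    expect_equal(unname(seqs[txt$transcript_id == "TM"]), "CGTT")
    expect_equal(unname(seqs[txt$transcript_id == "T2"]), "ACGTAAGGTT")
    expect_equal(txt$spliced_length[txt$transcript_id == "T2"], 10L)

    # genes sorted by id regardless of GTF row order
    expect_equal(as.data.frame(geneTable(models))$gene_id,
                 c("G2", "GM", "GP"))
})

test_that("parsing fails cleanly on inconsistent input", {
    tx <- list(list(transcript_id = "T1", gene_id = "G1",
                    biotype = "lincRNA", strand = "+",
                    exons = list(c(5, 40))))
    fa <- writeToyFasta(strrep("A", 20))
    gtf <- writeToyGtf(tx)
    expect_error(readGeneModels(gtf, fa), "T1")
    gtf2 <- writeToyGtf(tx, chrom = "chrMissing")
    expect_error(readGeneModels(gtf2, fa), "chrMissing")
})

test_that("lncRNA set construction applies every exclusion rule once", {
    genome <- strrep("ACGTGTCAAT", 400)
    mk <- function(id, biotype, strand, from, len = 300, tid = NULL) {
        list(transcript_id = if (is.null(tid)) paste0(id, ".t") else tid,
             gene_id = id, gene_name = paste0("sym", id), biotype = biotype,
             strand = strand, exons = list(c(from, from + len - 1)))
    }
    tx <- list(
        mk("KEEP", "lincRNA", "+", 1),
        mk("MIXED", "lincRNA", "+", 400, tid = "MIXED.t1"),
        mk("MIXED", "protein_coding", "+", 400, tid = "MIXED.t2"),
        mk("SHORT", "lincRNA", "+", 800, len = 150),
        mk("PSEUDO", "transcribed_unprocessed_pseudogene", "+", 1200),
        mk("SYM", "antisense", "-", 1600),
        mk("PROC", "processed_transcript", "+", 2000))
    models <- toyModels(genome, tx)
    res <- selectLncrnaGenes(models, codingSymbols = c("SYMSYM"))
    kept <- as.data.frame(geneTable(res$models))$gene_id
    expect_setequal(kept, c("KEEP", "PROC"))
    ex <- res$report@excluded
    expect_equal(ex$reason[ex$gene_id == "MIXED"], "non-lnc biotype")
    expect_equal(ex$reason[ex$gene_id == "SHORT"], "isoform <200 nt")
    expect_equal(ex$reason[ex$gene_id == "PSEUDO"], "pseudogene")
    expect_equal(ex$reason[ex$gene_id == "SYM"], "coding symbol")

    # report counts are consistent
    expect_equal(res$report@nGenesIn, 6L)
    expect_equal(res$report@nLncrnaGenes, 2L)

    # idempotence: filtering the filtered set changes nothing
    res2 <- selectLncrnaGenes(res$models, codingSymbols = c("SYMSYM"))
    expect_equal(as.data.frame(geneTable(res2$models))$gene_id, sort(kept))
    expect_equal(nrow(res2$report@excluded), 0L)
})

test_that("intergenic selection measures span gaps, strand-ignored", {
    genome <- strrep("A", 60000)
    mk <- function(id, from, to, biotype = "lincRNA", strand = "+")
        list(transcript_id = paste0(id, ".t"), gene_id = id,
             biotype = biotype, strand = strand, exons = list(c(from, to)))
    # 0-based spans: LNC1 [1000,2000) vs CODA [15000,16000): gap 13000
    # LNC2 [30000,30500) vs CODB [39500,39600): gap 9000
    # LNC3 overlaps CODC
    tx <- list(mk("LNC1", 1001, 2000),
               mk("LNC2", 30001, 30500),
               mk("LNC3", 55001, 55400),
               mk("CODA", 15001, 16000, biotype = "protein_coding"),
               mk("CODB", 39501, 39600, biotype = "protein_coding",
                  strand = "-"),
               mk("CODC", 55201, 55600, biotype = "protein_coding"))
    models <- toyModels(genome, tx)
    lnc <- selectLncrnaGenes(models)$models
    inter <- selectIntergenic(lnc, models, minSeparation = 10000L)
    expect_equal(as.data.frame(geneTable(inter))$gene_id, "LNC1")
    # LNC2's gap to CODB is 9000 < 10000 and LNC3 overlaps CODC
    inter0 <- selectIntergenic(lnc, models, minSeparation = 0L)
    expect_setequal(as.data.frame(geneTable(inter0))$gene_id,
                    c("LNC1", "LNC2"))
})

test_that("score-based subsetting keeps top-N with lexicographic ties", {
    genome <- strrep("ACGT", 2000)
    tx <- lapply(1:5, function(i)
        list(transcript_id = sprintf("T%d", i), gene_id = sprintf("G%d", i),
             biotype = "lincRNA", strand = "+",
             exons = list(c((i - 1) * 1500 + 1, (i - 1) * 1500 + 300))))
    models <- toyModels(genome, tx)
    scores <- setNames(c(1, 2, 3, 4, 5), paste0("G", 1:5))
    top2 <- subsetByScore(models, scores, 2)
    expect_setequal(as.data.frame(geneTable(top2))$gene_id, c("G4", "G5"))

    tied <- setNames(c(9, 9, 1, 1, 1), paste0("G", 1:5))
    top1 <- subsetByScore(models, tied, 1)
    expect_equal(as.data.frame(geneTable(top1))$gene_id, "G1")

    expect_equal(nrow(geneTable(subsetByScore(models, scores, 0))), 0L)
    expect_warning(subsetByScore(models, scores[1:3], 2), "without a score")
    expect_error(suppressWarnings(subsetByScore(models, scores[1:2], 3)),
                 "exceeds")
})
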