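test_that("identical configurations give byte-identical datasets", {
    cfg <- simConfig(seedRng = 13, nLncrnaGenes = 12, nCodingGenes = 3,
                     nSeedFamiliesConserved = 5, nSeedFamiliesNonconserved = 2,
                     plantedEnrichment = 1.5)
    d1 <- file.path(tempdir(), "det1")
    d2 <- file.path(tempdir(), "det2")
    unlink(c(d1, d2), recursive = TRUE)
    generateDataset(cfg, d1)
    generateDataset(cfg, d2)
    f1 <- sort(list.files(d1))
    expect_equal(f1, sort(list.files(d2)))
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
})

test_that("planted sites are literally present at their recorded loci", {
    sim <- localSimData(seedRng = 5, plantedEnrichment = 1.8, nLnc = 40,
                        nFam = 8)
    pl <- plantedSites(sim$truth)
    expect_gt(nrow(pl), 0)
    fam <- as.data.frame(familyTable(sim$families))
    seqs <- as.character(splicedSeqs(sim$models))
    names(seqs) <- as.data.frame(transcriptTable(sim$models))$transcript_id
    for (i in seq_len(nrow(pl))) {
        seed <- fam$seed[fam$family == pl$family[i]]
        want <- paste0(oracleRevcomp(seed), "A")
        got <- substr(seqs[[pl$transcript_id[i]]],
                      pl$transcript_pos[i] + 1, pl$transcript_pos[i] + 8)
        expect_equal(got, want, label = paste("site", i))
    }
})

test_that("planted sites are intact in planted-tier clades and broken below", {
    sim <- localSimData(seedRng = 5, plantedEnrichment = 1.8, nLnc = 40,
                        nFam = 8)
    pl <- plantedSites(sim$truth)
    clades <- read.table(file.path(sim$dir, "clades.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
    # direct string comparison over the emitted MAF rows
    lines <- readLines(file.path(sim$dir, "alignment.maf"))
    sl <- grep("^s ", lines, value = TRUE)
    f <- do.call(rbind, strsplit(sl, "[ \t]+"))
    species <- sub("\\..*", "", f[, 2])
    start <- as.integer(f[, 3])
    seqrow <- f[, 7]

    exl <- exonsByTranscript(sim$models)
    txt <- as.data.frame(transcriptTable(sim$models))
    checked <- 0L
    for (i in seq_len(nrow(pl))) {
        ti <- match(pl$transcript_id[i], txt$transcript_id)
        e <- exl[[ti]]
        # genomic interval of the (single-exon) site
        widths <- GenomicRanges::width(e)
        cs <- cumsum(c(0L, widths))
        p <- pl$transcript_pos[i]
        k <- findInterval(p, cs)
        g1 <- if (txt$strand[ti] == "+")
            GenomicRanges::start(e)[k] - 1L + (p - cs[k])
        else GenomicRanges::end(e)[k] - (p - cs[k]) - 8L
        refRow <- which(species == "primate1" & start <= g1 &
                        start + nchar(seqrow) > g1)[1]
        rows <- which(start == start[refRow])  # all species of this block
        off <- g1 - start[refRow]
        refSite <- substr(seqrow[refRow], off + 1, off + 8)
        for (r in rows) {
            spSite <- substr(seqrow[r], off + 1, off + 8)
            cl <- clades$clade[match(species[r], clades$species)]
            if (cl %in% c("primate", "mammal")) {
                expect_equal(spSite, refSite,
                             label = paste(species[r], "site", i))
            } else {
                nm <- sum(strsplit(spSite, "")[[1]] !=
                          strsplit(refSite, "")[[1]])
                expect_gte(nm, 2)
            }
            checked <- checked + 1L
        }
    }
    expect_gt(checked, 0L)
})

test_that("MAF reference rows reconstruct the genome FASTA exactly", {
    sim <- localSimData(seedRng = 5, plantedEnrichment = 1.8, nLnc = 40,
                        nFam = 8)
    genome <- Biostrings::readDNAStringSet(file.path(sim$dir, "genome.fa"))
    lines <- readLines(file.path(sim$dir, "alignment.maf"))
    sl <- grep("^s primate1\\.", lines, value = TRUE)
    f <- do.call(rbind, strsplit(sl, "[ \t]+"))
    for (i in seq_len(nrow(f))) {
        st <- as.integer(f[i, 3])
        sz <- as.integer(f[i, 4])
        expect_equal(f[i, 7],
                     as.character(Biostrings::subseq(genome[[1]],
                                                     st + 1, st + sz)))
    }
    # loadMaf's own validation agrees
    expect_s4_class(sim$maf, "MafIndex")
})

test_that("a null configuration plants nothing and extremes fail loudly", {
    cfg <- simConfig(seedRng = 23, nLncrnaGenes = 10, nCodingGenes = 2,
                     nSeedFamiliesConserved = 4, nSeedFamiliesNonconserved = 2,
                     plantedEnrichment = 1)
    d <- file.path(tempdir(), "nullsim")
    unlink(d, recursive = TRUE)
    truth <- generateDataset(cfg, d)
    expect_equal(nrow(plantedSites(truth)), 0L)

    cfgBad <- simConfig(seedRng = 23, nLncrnaGenes = 4, nCodingGenes = 2,
                        nSeedFamiliesConserved = 4,
                        nSeedFamiliesNonconserved = 2,
                        lncLen = 200L, plantedEnrichment = 3000)
    expect_error(generateDataset(cfgBad, file.path(tempdir(), "badsim")),
                 "impossible enrichment")
})

test_that("configuration invariants are enforced", {
    expect_error(simConfig(cladeDivergence = c(primate = 0.3, mammal = 0.1,
                                               vertebrate = 0.4)),
                 "non-decreasing")
    expect_error(simConfig(plantedEnrichment = -1), ">= 0")
    expect_error(simConfig(plantedSiteTier = "fish"),
                 "primate, mammal or vertebrate")
    expect_error(simConfig(nLncrnaGenes = 0), ">= 1")
})
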