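# a single-transcript model whose sequence carries one let-7 8mer, plus
# a MAF block over the locus built from per-species mutation positions
consFixture <- function(speciesRows, refStart = 10, minFraction = 0.5) {
    refSeq <- "GGGGGCTACCTCAGGGGG"  # 8mer at local offset 5
    dir <- newDir()
    genome <- paste0(strrep("A", refStart), refSeq, strrep("A", 10))
    fa <- writeToyFasta(genome, dir = dir)
    gtf <- writeToyGtf(list(list(transcript_id = "T1", gene_id = "G1",
                                 biotype = "lincRNA", strand = "+",
                                 exons = list(c(refStart + 1,
                                                refStart + nchar(refSeq))))),
                       dir = dir)
    models <- readGeneModels(gtf, fa)
    rows <- c(ref = refSeq, speciesRows)
    names(rows)[1] <- "primate1"
    maf <- writeToyMaf(rows, refStart, dir = dir)
    clades <- toyCladeTable(
        c("primate1", "primate2", "primate3",
          "mammal1", "mammal2", "mammal3", "mammal4", "mammal5",
          "vert1", "vert2"),
        c(rep("primate", 3), rep("mammal", 5), rep("vertebrate", 2)),
        dir = dir)
    index <- loadMaf(maf, clades, fasta = fa)
    sites <- scanTranscripts(models, seedFamilySet("let-7", "GAGGUAG"))
    called <- callSiteConservation(sites, index,
                                   consConfig(minFraction = minFraction))
    called[called$site_type == "8mer", , drop = FALSE]
}

breakSite <- function(ref = "GGGGGCTACCTCAGGGGG") {
    # two substitutions inside the 8mer
    paste0(substr(ref, 1, 5), "CTAGGTCA", substr(ref, 14, nchar(ref)))
}

test_that("MAF loading, querying and validation behave", {
    refSeq <- "GGGGGCTACCTCAGGGGG"
    dir <- newDir()
    fa <- writeToyFasta(paste0(strrep("A", 10), refSeq, strrep("A", 10)),
                        dir = dir)
    rows <- c(primate1 = refSeq, primate2 = refSeq, mammal1 = breakSite())
    maf <- writeToyMaf(rows, 10, dir = dir)
    clades <- toyCladeTable(c("primate1", "primate2", "mammal1"),
                            c("primate", "primate", "mammal"), dir = dir)
    index <- loadMaf(maf, clades, fasta = fa)
    q <- queryMaf(index, "chrT", 15, 23)
    expect_length(q, 3)
    expect_equal(unique(nchar(q)), 8L)
    expect_equal(unname(q["primate1"]), "CTACCTCA")

    # query outside any block is an empty (unalignable) result
    expect_length(queryMaf(index, "chrT", 0, 8), 0)

    # reference row disagreeing with the FASTA is an error with coords
    badfa <- writeToyFasta(strrep("T", 40), dir = newDir())
    expect_error(loadMaf(maf, clades, fasta = badfa), "chrT:11-28")

    # unmapped species is an error naming it
    clades2 <- toyCladeTable(c("primate1", "primate2"),
                             c("primate", "primate"), dir = newDir())
    expect_error(loadMaf(maf, clades2), "mammal1")
})

test_that("clade tiers follow the intact-fraction threshold rule", {
    ok <- "GGGGGCTACCTCAGGGGG"
    # all primates + 4/5 mammals intact, no vertebrates -> mammal tier
    call <- consFixture(c(primate2 = ok, primate3 = ok,
                          mammal1 = ok, mammal2 = ok, mammal3 = ok,
                          mammal4 = ok, mammal5 = breakSite(),
                          vert1 = breakSite(), vert2 = breakSite()))
    expect_equal(call$tier, "mammal")
    expect_equal(call$frac_primate, 1)
    expect_equal(call$frac_mammal, 0.8)
    expect_equal(call$frac_vertebrate, 0)

    # intact only in the reference -> none
    call2 <- consFixture(c(primate2 = breakSite(), primate3 = breakSite(),
                           mammal1 = breakSite(), vert1 = breakSite()))
    expect_equal(call2$tier, "none")

    # intact everywhere -> vertebrate
    all_ok <- setNames(rep(ok, 9),
                       c("primate2", "primate3", "mammal1", "mammal2",
                         "mammal3", "mammal4", "mammal5", "vert1", "vert2"))
    call3 <- consFixture(all_ok)
    expect_equal(call3$tier, "vertebrate")

    # raising the threshold can only demote: 4/5 mammals < 0.9
    call4 <- consFixture(c(primate2 = ok, primate3 = ok,
                           mammal1 = ok, mammal2 = ok, mammal3 = ok,
                           mammal4 = ok, mammal5 = breakSite()),
                         minFraction = 0.9)
    expect_equal(call4$tier, "primate")
})

test_that("gaps and species absence are handled", {
    ok <- "GGGGGCTACCTCAGGGGG"
    gap <- "GGGGGCTA-CCTCAGGGG"  # gap inside the site; row length kept
    call <- consFixture(c(primate2 = gap, primate3 = ok, mammal1 = ok))
    # primate2's gapped row is not intact; primate fraction is 1/2
    expect_equal(call$frac_primate, 0.5)
    # mammal fraction counts only the observed mammal (1/1)
    expect_equal(call$frac_mammal, 1)
    expect_equal(call$tier, "mammal")

    # with absent species counting against, the mammal denominator is 5
    refSeq <- "GGGGGCTACCTCAGGGGG"
    dir <- newDir()
    fa <- writeToyFasta(paste0(strrep("A", 10), refSeq, strrep("A", 10)),
                        dir = dir)
    gtf <- writeToyGtf(list(list(transcript_id = "T1", gene_id = "G1",
                                 biotype = "lincRNA", strand = "+",
                                 exons = list(c(11, 28)))), dir = dir)
    models <- readGeneModels(gtf, fa)
    maf <- writeToyMaf(c(primate1 = refSeq, primate2 = refSeq,
                         mammal1 = refSeq), 10, dir = dir)
    clades <- toyCladeTable(
        c("primate1", "primate2", "mammal1", "mammal2", "mammal3",
          "mammal4", "mammal5", "vert1"),
        c(rep("primate", 2), rep("mammal", 5), "vertebrate"), dir = dir)
    index <- loadMaf(maf, clades, fasta = fa)
    sites <- scanTranscripts(models, seedFamilySet("let-7", "GAGGUAG"))
    pick8 <- function(x) x[x$site_type == "8mer", , drop = FALSE]
    lenient <- pick8(callSiteConservation(sites, index, consConfig()))
    strict <- pick8(callSiteConservation(
        sites, index, consConfig(absentCountsAgainst = TRUE)))
    expect_equal(lenient$tier, "mammal")   # 1/1 observed mammals
    expect_equal(strict$tier, "primate")   # 1/5 mammals
})

test_that("stratification is cumulative and monotone", {
    sites <- data.frame(
        tier = c("vertebrate", "primate", "none", "mammal"),
        site_type = c("8mer", "8mer", "8mer", "7mer-m8"))
    counts <- stratifySites(sites)
    get <- function(t, ty) counts$count[counts$tier == t &
                                        counts$site_type == ty]
    expect_equal(get("primate", "8mer"), 2)   # vertebrate + primate tiers
    expect_equal(get("mammal", "8mer"), 1)
    expect_equal(get("vertebrate", "8mer"), 1)
    expect_equal(get("primate", "7mer-m8"), 1)
    expect_equal(get("vertebrate", "7mer-m8"), 0)
    expect_equal(sum(stratifySites(sites[0, , drop = FALSE])$count), 0)

    # monotone non-increasing with stringency for every site type, on
    # random tier assignments
    set.seed(9)
    for (i in 1:20) {
        rs <- data.frame(
            tier = sample(c("none", "primate", "mammal", "vertebrate"),
                          50, replace = TRUE),
            site_type = sample(c("8mer", "7mer-m8", "7mer-A1"), 50,
                               replace = TRUE))
        cc <- stratifySites(rs)
        for (ty in unique(cc$site_type)) {
            v <- cc$count[cc$site_type == ty][
                match(c("primate", "mammal", "vertebrate"),
                      cc$tier[cc$site_type == ty])]
            expect_true(all(diff(v) <= 0))
        }
    }
})

test_that("planted sites are recovered at their planted tier", {
    sim <- localSimData(seedRng = 5, plantedEnrichment = 1.8, nLnc = 40,
                        nFam = 8)
    sites <- scanTranscripts(sim$models, sim$families)
    called <- callSiteConservation(sites, sim$maf, consConfig())
    pl <- plantedSites(sim$truth)
    expect_gt(nrow(pl), 0)
    hit <- merge(pl, called,
                 by.x = c("transcript_id", "transcript_pos", "family"),
                 by.y = c("transcript_id", "transcript_pos", "family"))
    expect_equal(nrow(hit), nrow(pl))
    expect_true(all(hit$site_type == "8mer"))
    expect_gte(mean(hit$tier.y == "mammal"), 0.95)
})
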