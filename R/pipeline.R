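#' @include AllClasses.R annotation.R seeds.R maf.R conservation.R background.R enrichment.R localization.R
NULL

.subsetByTranscripts <- function(models, transcriptIds) {
    keep <- models@transcripts$transcript_id %in% transcriptIds
    tx <- models@transcripts[keep, , drop = FALSE]
    new("TranscriptModels",
        transcripts = tx,
        exons = models@exons[keep],
        sequences = models@sequences[keep],
        regions = models@regions[
            models@regions$transcript_id %in% tx$transcript_id, , drop = FALSE],
        genes = models@genes[models@genes$gene_id %in% tx$gene_id, ,
                             drop = FALSE])
}

#' Enrichment analysis for one transcript set
#'
#' Runs the complete observed-versus-null comparison on a set of
#' transcripts: scans the real seed families, calls conservation,
#' fits the dinucleotide model to the real seeds, draws random seed
#' sets, pushes them through the identical scan and conservation
#' path, and computes per-stratum enrichment statistics.
#'
#' @param models a \linkS4class{TranscriptModels} (already subset to
#'   the transcripts under analysis).
#' @param families a \linkS4class{SeedFamilySet}.
#' @param mafIndex a \linkS4class{MafIndex}.
#' @param config a \linkS4class{ConservationConfig}.
#' @param familyClass which family class carries the signal
#'   ("conserved" or "nonconserved").
#' @param region optional region filter ("UTR3", "CDS", ...).
#' @param nRandomSets number of random seed sets (default 20).
#' @param rngSeed RNG seed for the null sampling.
#' @return A list: \code{table} (the per-stratum enrichment table),
#'   \code{sites} (observed conservation-called sites),
#'   \code{observedCounts}, \code{nullCounts}, \code{seedSets},
#'   \code{model}.
#' @export
enrichmentAnalysis <- function(models, families, mafIndex,
                               config = consConfig(),
                               familyClass = "conserved",
                               region = NULL,
                               nRandomSets = 20L, rngSeed = 1L) {
    fam <- familyTable(families)
    real <- fam[fam$conservation_class == familyClass, , drop = FALSE]
    if (nrow(real) == 0) .stopf("no families of class '%s'", familyClass)

    patterns <- .patternTable(real$family, real$seed, set_id = "observed",
                              conservation_class = familyClass)
    sites <- .mapAndConserve(models, patterns, mafIndex, config)
    osites <- if (is.null(region)) sites else
        sites[sites$region %in% region, , drop = FALSE]
    observedCounts <- stratifySites(osites)

    model <- fitDinucModel(real$seed)
    seedSets <- sampleSeedSets(model, nSets = nRandomSets,
                               setSize = nrow(real),
                               realSeeds = fam$seed, rngSeed = rngSeed)
    nullCounts <- expectedCounts(seedSets, models, mafIndex, config, region)

    list(table = enrichmentTable(observedCounts, nullCounts),
         sites = sites,
         observedCounts = observedCounts,
         nullCounts = nullCounts,
         seedSets = seedSets,
         model = model)
}

#' Validate pipeline inputs for cross-consistency
#'
#' Checks GTF/FASTA/MAF contig and coordinate consistency, seed
#' alphabet, and clade-table coverage of the alignment species.
#' Problems are reported, not thrown.
#'
#' @param gtf,fasta,maf,clades,seeds,counts input file paths
#'   (\code{counts} optional).
#' @return data.frame with columns \code{check}, \code{severity}
#'   ("fatal" or "warning") and \code{message}; zero rows when all
#'   checks pass.
#' @export
validateInputs <- function(gtf, fasta, maf, clades, seeds, counts = NULL) {
    findings <- list()
    add <- function(check, severity, msg)
        findings[[length(findings) + 1L]] <<-
            data.frame(check = check, severity = severity, message = msg,
                       stringsAsFactors = FALSE)
    for (p in c(gtf, fasta, maf, clades, seeds))
        if (!file.exists(p)) add("files", "fatal", paste("missing file:", p))
    if (length(findings) > 0) return(do.call(rbind, findings))

    genome <- tryCatch(Biostrings::readDNAStringSet(fasta), error = function(e) {
        add("fasta", "fatal", conditionMessage(e)); NULL })
    if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
    gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                   error = function(e) {
        add("gtf", "fatal", conditionMessage(e)); NULL })
    if (!is.null(gr) && !is.null(genome)) {
        ctg <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                       names(genome))
        for (ch in ctg)
            add("gtf-fasta", "fatal",
                sprintf("GTF contig '%s' absent from FASTA", ch))
    }
    cl <- tryCatch(readCladeTable(clades), error = function(e) {
        add("clades", "fatal", conditionMessage(e)); NULL })
    if (!is.null(cl)) {
        idx <- tryCatch(loadMaf(maf, cl, fasta = fasta), error = function(e) {
            add("maf", "fatal", conditionMessage(e)); NULL })
        if (!is.null(idx)) {
            extra <- setdiff(cl$species, idx@species)
            if (length(extra) > 0)
                add("clades", "warning",
                    sprintf("clade table species never seen in MAF: %s",
                            paste(extra, collapse = ", ")))
        }
    }
    tryCatch(invisible(readSeedFamilies(seeds)), error = function(e)
        add("seeds", "fatal", conditionMessage(e)))
    if (!is.null(counts))
        tryCatch(invisible(readFractionCounts(counts)), error = function(e)
            add("counts", "fatal", conditionMessage(e)))
    if (length(findings) == 0)
        data.frame(check = character(0), severity = character(0),
                   message = character(0), stringsAsFactors = FALSE)
    else do.call(rbind, findings)
}

#' Run the full analysis pipeline
#'
#' Orchestrates annotation filtering, localization, site scanning,
#' conservation calling, the dinucleotide null, and enrichment
#' statistics over a grid of transcript subsets and family classes.
#' Deterministic given \code{rngSeed}.
#'
#' @param gtf,fasta,maf,clades,seeds,counts input file paths.
#' @param codingSymbols optional path to a coding-gene symbol list
#'   (one symbol per line).
#' @param config a \linkS4class{ConservationConfig}.
#' @param minSeparation intergenic separation threshold (nt).
#' @param minIsoformLength minimum isoform length (nt).
#' @param minTotalReads localization depth filter.
#' @param nRandomSets random seed sets per family class.
#' @param rngSeed RNG seed.
#' @param subsets transcript subsets to analyse; any of
#'   \code{lnc_all}, \code{lnc_intergenic}, \code{lnc_cytoplasmic},
#'   \code{coding_utr3}, \code{coding_cds}.
#' @param familyClasses family classes to analyse.
#' @param outDir optional directory for TSV outputs and run metadata.
#' @param verbose log stage-level record counts.
#' @return A list with \code{enrichment} (full grid table),
#'   \code{siteReport} (mammal-tier 8mer sites in cytoplasmic
#'   intergenic lncRNAs, the most stringent stratum),
#'   \code{localization}, \code{lncReport}, and \code{metadata}.
#' @export
runPipeline <- function(gtf, fasta, maf, clades, seeds, counts,
                        codingSymbols = NULL,
                        config = consConfig(),
                        minSeparation = 10000L,
                        minIsoformLength = 200L,
                        minTotalReads = 20L,
                        nRandomSets = 20L,
                        rngSeed = 1L,
                        subsets = c("lnc_all", "lnc_intergenic",
                                    "lnc_cytoplasmic", "coding_utr3",
                                    "coding_cds"),
                        familyClasses = c("conserved", "nonconserved"),
                        outDir = NULL, verbose = TRUE) {
    for (stage in list(c("annotation", gtf), c("annotation", fasta),
                       c("conservation", maf), c("conservation", clades),
                       c("seed_sites", seeds), c("localization", counts)))
        if (!file.exists(stage[2]))
            .stopf("%s: input file not found: %s", stage[1], stage[2])

    .msg(verbose, "annotation: parsing %s", gtf)
    models <- readGeneModels(gtf, fasta)
    .msg(verbose, "annotation: %d genes / %d transcripts in",
         nrow(models@genes), nrow(models@transcripts))

    symbols <- if (!is.null(codingSymbols)) readLines(codingSymbols)
               else character(0)
    sel <- selectLncrnaGenes(models, symbols,
                             minIsoformLength = minIsoformLength)
    lnc <- sel$models
    .msg(verbose, "annotation: %d lncRNA genes / %d transcripts retained",
         nrow(lnc@genes), nrow(lnc@transcripts))
    inter <- selectIntergenic(lnc, models, minSeparation = minSeparation)
    .msg(verbose, "annotation: %d intergenic lncRNA genes / %d transcripts",
         nrow(inter@genes), nrow(inter@transcripts))
    report <- sel$report
    report@nIntergenicGenes <- nrow(inter@genes)
    report@nIntergenicTranscripts <- nrow(inter@transcripts)

    .msg(verbose, "localization: classifying from %s", counts)
    se <- readFractionCounts(counts)
    calls <- classifyLocalization(se, minTotalReads = minTotalReads)
    cyto <- intersectCytoplasmic(inter, calls)
    .msg(verbose, "localization: %d of %d intergenic lncRNAs cytoplasmic",
         nrow(cyto@genes), nrow(inter@genes))

    .msg(verbose, "conservation: indexing %s", maf)
    cladeTab <- readCladeTable(clades)
    mafIndex <- loadMaf(maf, cladeTab, fasta = fasta)
    families <- readSeedFamilies(seeds)

    codingTx <- unique(models@regions$transcript_id)
    subsetDefs <- list(
        lnc_all = list(tx = lnc@transcripts$transcript_id, region = NULL),
        lnc_intergenic = list(tx = inter@transcripts$transcript_id,
                              region = NULL),
        lnc_cytoplasmic = list(tx = cyto@transcripts$transcript_id,
                               region = NULL),
        coding_utr3 = list(tx = codingTx, region = "UTR3"),
        coding_cds = list(tx = codingTx, region = "CDS"))
    subsetDefs <- subsetDefs[subsets]

    allTx <- unique(unlist(lapply(subsetDefs, `[[`, "tx")))
    mm <- .subsetByTranscripts(models, allTx)

    fam <- familyTable(families)
    enrich <- list()
    reportSites <- NULL
    for (ci in seq_along(familyClasses)) {
        cls <- familyClasses[ci]
        real <- fam[fam$conservation_class == cls, , drop = FALSE]
        if (nrow(real) == 0) next
        .msg(verbose, "background: sampling %d random sets of %d seeds (%s)",
             nRandomSets, nrow(real), cls)
        model <- fitDinucModel(real$seed)
        sets <- sampleSeedSets(model, nSets = nRandomSets,
                               setSize = nrow(real), realSeeds = fam$seed,
                               rngSeed = rngSeed + ci - 1L)
        patterns <- rbind(
            .patternTable(real$family, real$seed, set_id = "observed",
                          conservation_class = cls),
            .patternTable(sets$family, sets$seed,
                          set_id = as.character(sets$set_index),
                          conservation_class = cls))
        .msg(verbose, "seed_sites: scanning %d patterns over %d transcripts",
             nrow(patterns), length(mm))
        sites <- .mapAndConserve(mm, patterns, mafIndex, config)
        obs <- sites[sites$set_id == "observed", , drop = FALSE]
        nul <- sites[sites$set_id != "observed", , drop = FALSE]
        for (sn in names(subsetDefs)) {
            def <- subsetDefs[[sn]]
            inTx <- function(s) {
                sel <- s$transcript_id %in% def$tx
                if (!is.null(def$region)) sel <- sel & s$region %in% def$region
                s[sel, , drop = FALSE]
            }
            o <- stratifySites(inTx(obs))
            nu <- stratifySites(inTx(nul), by = "set_id",
                                byLevels = as.character(seq_len(nRandomSets)))
            names(nu)[1] <- "set_index"
            tab <- enrichmentTable(o, nu)
            tab <- cbind(data.frame(subset = sn, family_class = cls,
                                    stringsAsFactors = FALSE), tab)
            enrich[[paste(sn, cls)]] <- tab
        }
        if (cls == "conserved" && "lnc_cytoplasmic" %in% names(subsetDefs)) {
            cs <- obs[obs$transcript_id %in%
                          subsetDefs$lnc_cytoplasmic$tx &
                      obs$site_type == "8mer" &
                      .tierRank(obs$tier) >= .tierRank("mammal"), ,
                      drop = FALSE]
            gn <- stats::setNames(models@genes$gene_name,
                                  models@genes$gene_id)
            reportSites <- siteReport(cs, gn)
        }
    }
    enrichment <- do.call(rbind, enrich)
    rownames(enrichment) <- NULL

    metadata <- list(rng_seed = rngSeed, n_random_sets = nRandomSets,
                     min_separation = minSeparation,
                     min_isoform_length = minIsoformLength,
                     min_total_reads = minTotalReads,
                     min_clade_fraction = config@minFraction,
                     package_version = as.character(
                         utils::packageVersion("lncmir")))

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        .writeTsv(enrichment, file.path(outDir, "enrichment.tsv"))
        .writeTsv(calls, file.path(outDir, "localization.tsv"))
        if (!is.null(reportSites))
            .writeTsv(reportSites$table, file.path(outDir, "site_report.tsv"))
        .writeTsv(report@excluded, file.path(outDir, "excluded_genes.tsv"))
        writeLines(paste(names(metadata),
                         vapply(metadata, as.character, character(1)),
                         sep = "\t"),
                   file.path(outDir, "run_metadata.tsv"))
    }
    list(enrichment = enrichment, siteReport = reportSites,
         localization = calls, lncReport = report, metadata = metadata)
}

#' Simulate a dataset and analyse it end to end
#'
#' Convenience wrapper for calibration studies: generates a synthetic
#' dataset from \code{config}, re-reads every emitted file through the
#' standard parsers, applies the annotation filters, and runs
#' \code{\link{enrichmentAnalysis}} on the intergenic lncRNA set.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param rngSeed seed for the null seed-set sampling.
#' @param dir working directory for the emitted files (a temporary
#'   directory by default; removed afterwards unless supplied).
#' @param familyClass family class to analyse.
#' @return A list with \code{table} (enrichment table over tiers and
#'   site types), \code{truth} (the \linkS4class{GroundTruth}), and
#'   \code{nIntergenic} (genes analysed).
#' @export
simulateAndAnalyze <- function(config, rngSeed = 1L, dir = NULL,
                               familyClass = "conserved") {
    cleanup <- is.null(dir)
    if (is.null(dir)) dir <- tempfile("lncmir_sim")
    truth <- generateDataset(config, dir)
    models <- readGeneModels(file.path(dir, "annotation.gtf"),
                             file.path(dir, "genome.fa"))
    clades <- readCladeTable(file.path(dir, "clades.tsv"))
    mafIndex <- loadMaf(file.path(dir, "alignment.maf"), clades,
                        fasta = file.path(dir, "genome.fa"))
    families <- readSeedFamilies(file.path(dir, "seeds.tsv"))
    sel <- selectLncrnaGenes(models,
                             readLines(file.path(dir, "coding_symbols.txt")))
    inter <- selectIntergenic(sel$models, models)
    res <- enrichmentAnalysis(inter, families, mafIndex,
                              familyClass = familyClass, rngSeed = rngSeed)
    if (cleanup) unlink(dir, recursive = TRUE)
    list(table = res$table, truth = truth,
         nIntergenic = nrow(inter@genes))
}
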