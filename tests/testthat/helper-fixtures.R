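# Toy fixture builders used across the suite. Everything is generated
# in code at test time; nothing is stored on disk.

newDir <- function() {
    d <- tempfile("toyfix")
    dir.create(d)
    d
}

# write a FASTA with a single contig
writeToyFasta <- function(seq, chrom = "chrT", dir = newDir()) {
    path <- file.path(dir, "toy.fa")
    writeLines(c(paste0(">", chrom), seq), path)
    path
}

# write a GENCODE-dialect GTF from a transcript table:
# tx: list of lists with fields transcript_id, gene_id, gene_name,
# biotype, strand, exons (list of c(start1, end1), 1-based inclusive),
# and optionally cds (c(start1, end1) genomic span)
writeToyGtf <- function(tx, chrom = "chrT", dir = newDir()) {
    path <- file.path(dir, "toy.gtf")
    lines <- character(0)
    for (t in tx) {
        gname <- if (is.null(t$gene_name)) t$gene_id else t$gene_name
        attrs <- sprintf(
            'gene_id "%s"; gene_type "%s"; gene_name "%s"; transcript_id "%s"; transcript_type "%s";',
            t$gene_id, t$biotype, gname, t$transcript_id, t$biotype)
        span <- range(unlist(t$exons))
        lines <- c(lines, sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                                  chrom, span[1], span[2], t$strand, attrs))
        for (e in t$exons)
            lines <- c(lines, sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                                      chrom, e[1], e[2], t$strand, attrs))
        if (!is.null(t$cds))
            lines <- c(lines, sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                      chrom, t$cds[1], t$cds[2], t$strand,
                                      attrs))
    }
    writeLines(lines, path)
    path
}

# build TranscriptModels straight from a genome string and tx table
toyModels <- function(seq, tx, chrom = "chrT") {
    dir <- newDir()
    readGeneModels(writeToyGtf(tx, chrom, dir),
                   writeToyFasta(seq, chrom, dir))
}

# write a MAF with one block; rows: named character vector of gapped
# sequences (first must be the reference), refStart 0-based
writeToyMaf <- function(rows, refStart, chrom = "chrT",
                        dir = newDir(), srcSize = 10000) {
    path <- file.path(dir, "toy.maf")
    size <- nchar(gsub("-", "", rows[[1]]))
    lines <- c("##maf version=1", "", "a score=0",
               sprintf("s %s.%s %d %d + %d %s", names(rows), chrom,
                       refStart, size, srcSize, unname(rows)), "")
    writeLines(lines, path)
    path
}

toyCladeTable <- function(species, clade, dir = newDir()) {
    path <- file.path(dir, "clades.tsv")
    write.table(data.frame(species = species, clade = clade),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    readCladeTable(path)
}

# a small simulated dataset shared by several tests (generated once)
localSimData <- local({
    cache <- new.env()
    function(seedRng = 5, plantedEnrichment = 1.8, nLnc = 40, nFam = 8,
             ...) {
        key <- paste(seedRng, plantedEnrichment, nLnc, nFam, ...)
        if (!is.null(cache[[key]])) return(cache[[key]])
        dir <- file.path(tempdir(), paste0("simdata_", abs(sum(utf8ToInt(key)))))
        cfg <- simConfig(seedRng = seedRng, nLncrnaGenes = nLnc,
                         nCodingGenes = 5, nSeedFamiliesConserved = nFam,
                         nSeedFamiliesNonconserved = 3,
                         plantedEnrichment = plantedEnrichment, ...)
        truth <- generateDataset(cfg, dir)
        models <- readGeneModels(file.path(dir, "annotation.gtf"),
                                 file.path(dir, "genome.fa"))
        clades <- readCladeTable(file.path(dir, "clades.tsv"))
        maf <- loadMaf(file.path(dir, "alignment.maf"), clades,
                       fasta = file.path(dir, "genome.fa"))
        families <- readSeedFamilies(file.path(dir, "seeds.tsv"))
        out <- list(dir = dir, cfg = cfg, truth = truth, models = models,
                    clades = clades, maf = maf, families = families)
        cache[[key]] <- out
        out
    }
})
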