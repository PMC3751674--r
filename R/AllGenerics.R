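#' @include AllClasses.R
NULL

#' Accessors for lncmir containers
#'
#' \code{familyTable} returns the family/seed/class table of a
#' \linkS4class{SeedFamilySet}; \code{transcriptTable},
#' \code{geneTable}, \code{splicedSeqs}, \code{exonsByTranscript} and
#' \code{regionTable} expose the slots of a
#' \linkS4class{TranscriptModels} object.
#'
#' @param x the object.
#' @return The corresponding table, \code{GRangesList} or
#'   \code{DNAStringSet}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))

#' @rdname accessors
#' @export
setMethod("familyTable", "SeedFamilySet", function(x) x@families)

#' @rdname accessors
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))

#' @rdname accessors
#' @export
setMethod("transcriptTable", "TranscriptModels", function(x) x@transcripts)

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname accessors
#' @export
setMethod("geneTable", "TranscriptModels", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("splicedSeqs", function(x) standardGeneric("splicedSeqs"))

#' @rdname accessors
#' @export
setMethod("splicedSeqs", "TranscriptModels", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))

#' @rdname accessors
#' @export
setMethod("exonsByTranscript", "TranscriptModels", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setMethod("regionTable", "TranscriptModels", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("plantedSites", function(x) standardGeneric("plantedSites"))

#' @rdname accessors
#' @export
setMethod("plantedSites", "GroundTruth", function(x) x@plantedSites)

#' @rdname accessors
#' @export
setGeneric("trueCytoplasmicGenes",
           function(x) standardGeneric("trueCytoplasmicGenes"))

#' @rdname accessors
#' @export
setMethod("trueCytoplasmicGenes", "GroundTruth",
          function(x) x@trueCytoplasmicGenes)

#' Enrichment accessors
#'
#' Scalar accessors for \linkS4class{EnrichmentResult}.
#'
#' @param x an \linkS4class{EnrichmentResult}.
#' @return A scalar.
#' @name enrichment-accessors
NULL

#' @rdname enrichment-accessors
#' @export
setGeneric("enrichmentRatio", function(x) standardGeneric("enrichmentRatio"))

#' @rdname enrichment-accessors
#' @export
setMethod("enrichmentRatio", "EnrichmentResult", function(x) x@ratio)

#' @rdname enrichment-accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname enrichment-accessors
#' @export
setMethod("empiricalP", "EnrichmentResult", function(x) x@empiricalP)

#' @rdname enrichment-accessors
#' @export
setGeneric("falseDiscoveryRate",
           function(x) standardGeneric("falseDiscoveryRate"))

#' @rdname enrichment-accessors
#' @export
setMethod("falseDiscoveryRate", "EnrichmentResult", function(x) x@fdr)

setMethod("length", "TranscriptModels", function(x) nrow(x@transcripts))

setMethod("show", "SeedFamilySet", function(object) {
    df <- object@families
    cat("SeedFamilySet with", nrow(df), "families (",
        sum(df$conservation_class == "conserved"), "conserved,",
        sum(df$conservation_class == "nonconserved"), "nonconserved )\n")
})

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels:", nrow(object@transcripts), "transcripts in",
        nrow(object@genes), "genes on",
        length(unique(object@transcripts$chrom)), "sequence(s)\n")
})

setMethod("show", "MafIndex", function(object) {
    cat("MafIndex:", length(object@blocks), "blocks,",
        length(object@species), "species (reference:",
        object@reference, ")\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult: observed", object@observed,
        "expected", format(object@expected, digits = 4),
        "ratio", format(object@ratio, digits = 4),
        "P", format(object@empiricalP, digits = 3),
        "FDR", format(object@fdr, digits = 3),
        paste0("[", object@label, "]"), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seedRng, "|",
        object@nLncrnaGenes, "lncRNA +", object@nCodingGenes,
        "coding genes |", sum(object@nSpeciesPerClade), "species |",
        "planted", object@plantedEnrichment, "x at",
        object@plantedSiteTier, "tier\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@plantedSites), "planted sites,",
        length(object@trueCytoplasmicGenes), "cytoplasmic genes,",
        "analytic expected background count",
        format(object@expectedBackgroundCount, digits = 4), "\n")
})

setMethod("show", "LncrnaSetReport", function(object) {
    cat("LncrnaSetReport:", object@nGenesIn, "genes in ->",
        object@nLncrnaGenes, "lncRNA genes /",
        object@nLncrnaTranscripts, "transcripts")
    if (!is.na(object@nIntergenicGenes))
        cat(" ->", object@nIntergenicGenes, "intergenic genes /",
            object@nIntergenicTranscripts, "transcripts")
    cat("\n")
    if (nrow(object@excluded) > 0) {
        tab <- table(object@excluded$reason)
        for (r in names(tab)) cat("  excluded (", r, "): ", tab[[r]], "\n",
                                  sep = "")
    }
})
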