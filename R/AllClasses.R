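#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

CLADE_LEVELS <- c("primate", "mammal", "vertebrate")
TIER_LEVELS <- c("none", "primate", "mammal", "vertebrate")
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")
LNC_BIOTYPES <- c("antisense", "lincRNA", "non_coding", "processed_transcript")

#' SeedFamilySet: microRNA seed families
#'
#' Holds a set of microRNA families, each defined by its 7-nt seed
#' (microRNA positions 2-8, written 5'->3' in RNA alphabet) and a
#' conservation class (\code{conserved} families carry the putative
#' signal; \code{nonconserved} families serve as a negative control).
#'
#' @slot families A \code{DataFrame} with columns \code{family},
#'   \code{seed} (7-nt RNA string) and \code{conservation_class}.
#' @export
setClass("SeedFamilySet", representation(families = "DataFrame"))

setValidity("SeedFamilySet", function(object) {
    df <- object@families
    need <- c("family", "seed", "conservation_class")
    if (!all(need %in% colnames(df)))
        return(paste("families must have columns", paste(need, collapse = ", ")))
    if (any(nchar(df$seed) != 7L))
        return("every seed must be exactly 7 nt")
    if (any(grepl("[^ACGU]", df$seed)))
        return("seeds must use the RNA alphabet A/C/G/U")
    if (!all(df$conservation_class %in% c("conserved", "nonconserved")))
        return("conservation_class must be 'conserved' or 'nonconserved'")
    if (anyDuplicated(df$family))
        return("family names must be unique")
    TRUE
})

#' TranscriptModels: gene/transcript/exon models with spliced sequences
#'
#' The central annotation container: per-transcript exon structures
#' (ordered 5'->3' in transcript orientation), spliced sense-strand
#' sequences, optional CDS/UTR region maps in transcript coordinates,
#' and a gene-level table. All internal coordinates are 0-based
#' half-open; GTF input/output is 1-based inclusive.
#'
#' @slot transcripts \code{DataFrame}, one row per transcript:
#'   \code{transcript_id}, \code{gene_id}, \code{gene_name},
#'   \code{chrom}, \code{strand}, \code{biotype}, \code{spliced_length}.
#' @slot exons \code{GRangesList} parallel to \code{transcripts}; exon
#'   ranges are 1-based (GRanges convention) and ordered 5'->3' in
#'   transcript orientation.
#' @slot sequences \code{DNAStringSet} of spliced sense-strand sequences,
#'   parallel to \code{transcripts}.
#' @slot regions \code{DataFrame} with \code{transcript_id},
#'   \code{region} (UTR5/CDS/UTR3), \code{start}, \code{end}
#'   (0-based half-open transcript coordinates); empty for transcripts
#'   without CDS annotation.
#' @slot genes \code{DataFrame}, one row per gene: \code{gene_id},
#'   \code{gene_name}, \code{chrom}, \code{strand}, \code{start},
#'   \code{end} (0-based half-open span), \code{biotypes}
#'   (comma-collapsed set of transcript biotypes).
#' @export
setClass("TranscriptModels", representation(
    transcripts = "DataFrame",
    exons = "GRangesList",
    sequences = "DNAStringSet",
    regions = "DataFrame",
    genes = "DataFrame"
))

setValidity("TranscriptModels", function(object) {
    n <- nrow(object@transcripts)
    if (length(object@exons) != n || length(object@sequences) != n)
        return("exons and sequences must be parallel to the transcript table")
    exlen <- unname(sum(GenomicRanges::width(object@exons)))
    if (n > 0 && !all(exlen == object@transcripts$spliced_length))
        return("spliced_length must equal the sum of exon widths")
    if (n > 0 && !all(Biostrings::width(object@sequences) ==
                      object@transcripts$spliced_length))
        return("sequence widths must equal spliced_length")
    TRUE
})

#' MafIndex: queryable multiple sequence alignment
#'
#' A parsed multiple alignment (MAF) indexed by reference-genome
#' interval. Each block stores the per-species gapped rows and a map
#' from reference positions to alignment columns, supporting exact
#' per-site intactness queries.
#'
#' @slot blocks list of parsed blocks.
#' @slot blockRanges \code{GRanges} of reference intervals, one per block.
#' @slot species character vector of all species seen in the alignment.
#' @slot reference the reference species (first row of every block).
#' @slot clades data.frame mapping \code{species} to \code{clade}
#'   (primate / mammal / vertebrate, disjoint finest labels).
#' @export
setClass("MafIndex", representation(
    blocks = "list",
    blockRanges = "GRanges",
    species = "character",
    reference = "character",
    clades = "data.frame"
))

setValidity("MafIndex", function(object) {
    if (length(object@blocks) != length(object@blockRanges))
        return("blocks and blockRanges must be parallel")
    if (!all(c("species", "clade") %in% colnames(object@clades)))
        return("clades must have columns species, clade")
    if (!all(object@species %in% object@clades$species))
        return("every alignment species must be present in the clade table")
    if (!object@reference %in% object@clades$species)
        return("reference species missing from the clade table")
    TRUE
})

#' ConservationConfig: thresholds for clade-tier conservation calls
#'
#' @slot minFraction fraction of a clade group's aligned species that
#'   must carry an intact site for the clade to count (default 0.5).
#' @slot requireReference if TRUE (default) a site whose reference row
#'   does not carry the match gets tier \code{none}.
#' @slot absentCountsAgainst if TRUE, species missing from an alignment
#'   block count as non-intact instead of being dropped from the clade
#'   denominator.
#' @export
setClass("ConservationConfig", representation(
    minFraction = "numeric",
    requireReference = "logical",
    absentCountsAgainst = "logical"
))

setValidity("ConservationConfig", function(object) {
    if (length(object@minFraction) != 1 || object@minFraction <= 0 ||
        object@minFraction > 1)
        return("minFraction must be a single value in (0, 1]")
    TRUE
})

#' Construct a ConservationConfig
#'
#' @param minFraction per-clade intact fraction threshold in (0, 1].
#' @param requireReference require the reference species to carry the match.
#' @param absentCountsAgainst treat species absent from a block as
#'   non-intact rather than unobserved.
#' @return A \linkS4class{ConservationConfig}.
#' @export
consConfig <- function(minFraction = 0.5, requireReference = TRUE,
                       absentCountsAgainst = FALSE) {
    new("ConservationConfig", minFraction = minFraction,
        requireReference = requireReference,
        absentCountsAgainst = absentCountsAgainst)
}

#' DinucModel: first-order Markov model of seed composition
#'
#' @slot initial named length-4 probability vector over A/C/G/U for the
#'   first seed position (empirical, unsmoothed).
#' @slot transition 4x4 row-stochastic matrix of dinucleotide transition
#'   probabilities (add-one smoothed).
#' @export
setClass("DinucModel", representation(
    initial = "numeric",
    transition = "matrix"
))

setValidity("DinucModel", function(object) {
    if (!isTRUE(all.equal(sum(object@initial), 1)))
        return("initial distribution must sum to 1")
    if (!isTRUE(all.equal(unname(rowSums(object@transition)), rep(1, 4))))
        return("transition matrix rows must sum to 1")
    TRUE
})

#' EnrichmentResult: observed/expected statistics for one stratum
#'
#' @slot observed observed site count for the real seed set.
#' @slot randomCounts per-random-set site counts (typically 20).
#' @slot expected mean of \code{randomCounts}.
#' @slot ratio observed / expected (0 if observed is 0; NA if expected
#'   is 0 with observed > 0).
#' @slot meanOfRatios mean of per-set ratios observed / count, over sets
#'   with non-zero counts (secondary summary).
#' @slot nExceeding number of random sets with count >= observed (ties
#'   count as exceeding).
#' @slot empiricalP nExceeding / number of random sets.
#' @slot fdr expected / observed, capped at 1.
#' @slot label significance label under the 20-set rule ("P<=0.05",
#'   "P=0.10", "ns"; empty unless exactly 20 sets).
#' @slot reliable FALSE when expected < 1 (counts too low for a stable
#'   ratio; reported as n/a).
#' @export
setClass("EnrichmentResult", representation(
    observed = "numeric",
    randomCounts = "numeric",
    expected = "numeric",
    ratio = "numeric",
    meanOfRatios = "numeric",
    nExceeding = "integer",
    empiricalP = "numeric",
    fdr = "numeric",
    label = "character",
    reliable = "logical"
))

#' SimConfig: synthetic dataset configuration
#'
#' Describes a toy multi-species genome with clade-structured
#' substitution, coding genes (5'UTR + CDS + 3'UTR) and lncRNA genes,
#' microRNA seed families, target sites planted at a configurable
#' observed/expected enrichment factor, and nuclear/cytoplasmic
#' fraction counts. See \code{\link{simConfig}} for defaults.
#'
#' @slot seedRng integer RNG seed; identical configs give byte-identical
#'   output files.
#' @slot nSpeciesPerClade named integer vector (primate, mammal,
#'   vertebrate); the reference species is the first primate.
#' @slot nCodingGenes,nLncrnaGenes gene counts.
#' @slot utr5Len,utr3Len,cdsLen,lncLen region lengths in nucleotides.
#' @slot backgroundGc background GC fraction.
#' @slot cladeDivergence named numeric vector of per-site substitution
#'   probabilities, non-decreasing primate -> vertebrate.
#' @slot plantedEnrichment target observed/expected factor for conserved
#'   8mer sites at the planted tier (1 = null, nothing planted).
#' @slot plantedSiteTier clade tier at which planted sites are held
#'   intact ("primate", "mammal" or "vertebrate").
#' @slot nSeedFamiliesConserved,nSeedFamiliesNonconserved family counts.
#' @slot cytoBiasFraction fraction of lncRNA genes simulated as
#'   cytoplasm-enriched.
#' @slot minFraction clade intact-fraction threshold assumed when sizing
#'   the planted-site count analytically.
#' @slot intergenicGap baseline gap between adjacent genes (nt).
#' @slot cellLines cell line names for the fraction count matrix.
#' @slot meanDepth mean per-gene read depth per library.
#' @slot fracBias cytoplasm:nucleus fold bias applied to cytoplasmic
#'   genes (inverted for the rest).
#' @slot lowExprFraction fraction of genes simulated at near-zero
#'   expression to exercise the read-depth filter.
#' @slot nbDispersion negative binomial dispersion.
#' @slot twoExonFraction fraction of lncRNA genes given two exons.
#' @slot includeDecoys include a small fixed set of decoy genes that
#'   exercise every annotation exclusion rule.
#' @export
setClass("SimConfig", representation(
    seedRng = "integer",
    nSpeciesPerClade = "integer",
    nCodingGenes = "integer",
    nLncrnaGenes = "integer",
    utr5Len = "integer",
    utr3Len = "integer",
    cdsLen = "integer",
    lncLen = "integer",
    backgroundGc = "numeric",
    cladeDivergence = "numeric",
    plantedEnrichment = "numeric",
    plantedSiteTier = "character",
    nSeedFamiliesConserved = "integer",
    nSeedFamiliesNonconserved = "integer",
    cytoBiasFraction = "numeric",
    minFraction = "numeric",
    intergenicGap = "integer",
    cellLines = "character",
    meanDepth = "numeric",
    fracBias = "numeric",
    lowExprFraction = "numeric",
    nbDispersion = "numeric",
    twoExonFraction = "numeric",
    includeDecoys = "logical"
))

setValidity("SimConfig", function(object) {
    d <- object@cladeDivergence
    if (!identical(names(d), CLADE_LEVELS))
        return("cladeDivergence must be named primate, mammal, vertebrate")
    if (any(d < 0) || any(d > 0.5))
        return("cladeDivergence values must lie in [0, 0.5]")
    if (is.unsorted(d))
        return("cladeDivergence must be non-decreasing primate -> vertebrate")
    if (!identical(names(object@nSpeciesPerClade), CLADE_LEVELS))
        return("nSpeciesPerClade must be named primate, mammal, vertebrate")
    if (any(object@nSpeciesPerClade < 1L))
        return("need at least one species per clade")
    if (object@backgroundGc < 0 || object@backgroundGc > 1)
        return("backgroundGc must lie in [0, 1]")
    if (object@plantedEnrichment < 0)
        return("plantedEnrichment must be >= 0")
    if (!object@plantedSiteTier %in% CLADE_LEVELS)
        return("plantedSiteTier must be primate, mammal or vertebrate")
    counts <- c(object@nCodingGenes, object@nLncrnaGenes,
                object@nSeedFamiliesConserved, object@nSeedFamiliesNonconserved)
    if (any(counts < 1L))
        return("gene and family counts must be >= 1")
    if (length(object@cellLines) < 1L)
        return("at least one cell line is required")
    TRUE
})

#' GroundTruth: what the simulator actually planted
#'
#' @slot plantedSites data.frame with one row per planted site:
#'   \code{gene_id}, \code{transcript_id}, \code{transcript_pos}
#'   (0-based start in the spliced sequence), \code{family},
#'   \code{tier}.
#' @slot trueCytoplasmicGenes gene ids simulated as cytoplasm-enriched.
#' @slot analysisGenes lncRNA gene ids that survive all annotation
#'   filters by construction (the planting population).
#' @slot expectedBackgroundCount analytic expected count of
#'   clade-conserved 8mer background matches for the conserved families
#'   over \code{analysisGenes}, the \dQuote{E} used to size planting.
#' @export
setClass("GroundTruth", representation(
    plantedSites = "data.frame",
    trueCytoplasmicGenes = "character",
    analysisGenes = "character",
    expectedBackgroundCount = "numeric"
))

#' LncrnaSetReport: bookkeeping for lncRNA set construction
#'
#' @slot nGenesIn genes entering the filter.
#' @slot nLncrnaGenes,nLncrnaTranscripts retained after biotype /
#'   length / symbol filtering.
#' @slot nIntergenicGenes,nIntergenicTranscripts retained after the
#'   genomic-separation filter (NA until that filter has run).
#' @slot excluded data.frame of \code{gene_id}, \code{reason}.
#' @export
setClass("LncrnaSetReport", representation(
    nGenesIn = "integer",
    nLncrnaGenes = "integer",
    nLncrnaTranscripts = "integer",
    nIntergenicGenes = "integer",
    nIntergenicTranscripts = "integer",
    excluded = "data.frame"
))

setValidity("LncrnaSetReport", function(object) {
    if (!is.na(object@nLncrnaGenes) &&
        object@nGenesIn - object@nLncrnaGenes != nrow(object@excluded))
        return("excluded map inconsistent with gene counts")
    TRUE
})
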