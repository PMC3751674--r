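#' @include AllClasses.R conservation.R
NULL

#' Observed-to-expected enrichment for one stratum
#'
#' Compares an observed site count to the per-set counts obtained
#' from composition-matched random seed sets. The expected count is
#' the arithmetic mean of the random counts; the enrichment ratio is
#' observed/expected; the empirical P-value is the fraction of random
#' sets whose count is at least the observed count (ties count as
#' exceeding); the implied false discovery rate is expected/observed,
#' capped at 1 (the reciprocal of the ratio). A secondary
#' mean-of-per-set-ratios summary is also computed. With exactly 20
#' random sets the label follows the 19/20 and 18/20 rule:
#' \code{"P<=0.05"} when at most one set reaches the observed count,
#' \code{"P=0.10"} when exactly two do, otherwise \code{"ns"}.
#' A stratum whose expected count is below 1 is flagged unreliable
#' (too few counts for a stable ratio).
#'
#' @param observed observed site count (non-negative).
#' @param randomCounts per-random-set counts (non-negative; typically
#'   20 values).
#' @return An \linkS4class{EnrichmentResult}.
#' @examples
#' computeEnrichment(12, rep(20 / 3, 20))  # ratio 1.8, FDR 56%
#' @export
computeEnrichment <- function(observed, randomCounts) {
    if (length(randomCounts) < 1) .stopf("need at least one random count")
    if (observed < 0 || any(randomCounts < 0))
        .stopf("counts must be non-negative")
    expected <- mean(randomCounts)
    if (observed == 0) {
        ratio <- 0
        fdr <- 1
    } else if (expected == 0) {
        ratio <- NA_real_
        fdr <- NA_real_
    } else {
        ratio <- observed / expected
        fdr <- min(1, expected / observed)
    }
    nz <- randomCounts > 0
    meanOfRatios <- if (observed > 0 && any(nz))
        mean(observed / randomCounts[nz]) else NA_real_
    nExceeding <- sum(randomCounts >= observed)
    n <- length(randomCounts)
    empiricalP <- nExceeding / n
    label <- if (n == 20L) {
        if (nExceeding <= 1L) "P<=0.05"
        else if (nExceeding == 2L) "P=0.10"
        else "ns"
    } else ""
    new("EnrichmentResult",
        observed = as.numeric(observed),
        randomCounts = as.numeric(randomCounts),
        expected = expected,
        ratio = ratio,
        meanOfRatios = meanOfRatios,
        nExceeding = as.integer(nExceeding),
        empiricalP = empiricalP,
        fdr = fdr,
        label = label,
        reliable = expected >= 1)
}

#' Assemble an enrichment table over strata
#'
#' Joins observed stratum counts with per-set null counts and runs
#' \code{\link{computeEnrichment}} on every stratum.
#'
#' @param observedCounts data.frame with columns \code{tier},
#'   \code{site_type}, \code{count} (from \code{\link{stratifySites}}).
#' @param nullCounts data.frame with columns \code{set_index},
#'   \code{tier}, \code{site_type}, \code{count} (from
#'   \code{\link{expectedCounts}}).
#' @return data.frame with one row per stratum: observed, expected,
#'   ratio, mean_of_ratios, n_exceeding, empirical_p, fdr, label,
#'   reliable.
#' @export
enrichmentTable <- function(observedCounts, nullCounts) {
    out <- lapply(seq_len(nrow(observedCounts)), function(i) {
        tier <- observedCounts$tier[i]
        st <- observedCounts$site_type[i]
        rc <- nullCounts$count[nullCounts$tier == tier &
                               nullCounts$site_type == st]
        r <- computeEnrichment(observedCounts$count[i], rc)
        data.frame(tier = tier, site_type = st,
                   observed = r@observed, expected = r@expected,
                   ratio = r@ratio, mean_of_ratios = r@meanOfRatios,
                   n_exceeding = r@nExceeding, empirical_p = r@empiricalP,
                   fdr = r@fdr, label = r@label, reliable = r@reliable,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Gene-level site report
#'
#' Collapses a site table to one row per gene-level site (a site
#' shared by several isoforms of a gene counts once, keyed by genome
#' position and family), sorted by gene id then position. Genome
#' positions are reported 1-based.
#'
#' @param sites a site table (already filtered to the stratum of
#'   interest, e.g. mammal-tier 8mers in cytoplasmic intergenic
#'   lncRNAs).
#' @param geneNames optional named character vector mapping gene ids
#'   to symbols.
#' @return A list with \code{table} (gene_id, symbol, family,
#'   site_type, tier, chrom, genome_pos) and the summary counts
#'   \code{n_sites}, \code{n_genes}, \code{n_families}.
#' @export
siteReport <- function(sites, geneNames = NULL) {
    if (nrow(sites) == 0) {
        return(list(table = data.frame(gene_id = character(0),
                                       symbol = character(0),
                                       family = character(0),
                                       site_type = character(0),
                                       tier = character(0),
                                       chrom = character(0),
                                       genome_pos = integer(0)),
                    n_sites = 0L, n_genes = 0L, n_families = 0L))
    }
    tab <- data.frame(
        gene_id = sites$gene_id,
        symbol = if (!is.null(geneNames))
            unname(geneNames[sites$gene_id]) else sites$gene_id,
        family = sites$family,
        site_type = sites$site_type,
        tier = if ("tier" %in% names(sites)) sites$tier else NA_character_,
        chrom = sites$chrom,
        genome_pos = sites$genome_pos + 1L,
        stringsAsFactors = FALSE)
    key <- paste(tab$gene_id, tab$chrom, tab$genome_pos, tab$family,
                 sep = "\r")
    tab <- tab[!duplicated(key), , drop = FALSE]
    tab <- tab[order(tab$gene_id, tab$genome_pos), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab,
         n_sites = nrow(tab),
         n_genes = length(unique(tab$gene_id)),
         n_families = length(unique(tab$family)))
}
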