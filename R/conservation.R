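#' @include AllClasses.R maf.R seeds.R
NULL

## nested tier membership: which disjoint clade groups must pass for a
## given tier. Tier primate needs the primate group; tier mammal
## additionally the non-primate mammal group; tier vertebrate all three.
.tierRank <- function(tier) match(tier, TIER_LEVELS) - 1L

#' Call per-site clade-tier conservation
#'
#' For every target site, determines in which aligned species the
#' match is intact, and assigns the deepest nested clade tier
#' (primate < mammal < vertebrate) supported by the alignment. A
#' species is intact iff its aligned sequence over the site's
#' reference columns equals the site's match string exactly, with no
#' gaps in either row within the site. Per clade the intact fraction
#' is computed over the disjoint group of aligned species (non-
#' reference primates; non-primate placental mammals; non-mammal
#' vertebrates); a tier is reached when its own group and every
#' shallower group meet \code{minFraction}. Sites not covered by the
#' alignment get tier \code{none}.
#'
#' @param sites a site table from \code{\link{scanTranscripts}}.
#' @param index a \linkS4class{MafIndex}.
#' @param config a \linkS4class{ConservationConfig}.
#' @return The site table with added columns \code{tier},
#'   \code{frac_primate}, \code{frac_mammal}, \code{frac_vertebrate}
#'   and \code{n_species_intact}.
#' @export
callSiteConservation <- function(sites, index, config = consConfig()) {
    n <- nrow(sites)
    sites$tier <- rep("none", n)
    sites$frac_primate <- sites$frac_mammal <- sites$frac_vertebrate <-
        rep(NA_real_, n)
    sites$n_species_intact <- rep(0L, n)
    if (n == 0) return(sites)

    pieces <- attr(sites, "pieces")
    if (is.null(pieces)) .stopf("site table has lost its genomic pieces")
    pdf <- pieces
    pdf$chrom <- sites$chrom[pdf$site]

    pgr <- GenomicRanges::GRanges(pdf$chrom,
        IRanges::IRanges(pdf$gs + 1L, pdf$ge))
    hits <- GenomicRanges::findOverlaps(pgr, index@blockRanges,
                                        type = "within", select = "first")
    pdf$block <- hits

    allSpecies <- index@clades$species
    nsp <- length(allSpecies)
    ## intact status per (site x species); NA = not observed
    intact <- matrix(NA, nrow = n, ncol = nsp,
                     dimnames = list(NULL, allSpecies))
    refok <- rep(TRUE, n)
    covered <- rep(TRUE, n)
    covered[unique(pdf$site[is.na(pdf$block)])] <- FALSE

    ok <- !is.na(pdf$block) & covered[pdf$site]
    for (b in unique(pdf$block[ok])) {
        blk <- index@blocks[[b]]
        rows <- which(ok & pdf$block == b)
        off1 <- pdf$gs[rows] - blk$start + 1L
        off2 <- pdf$ge[rows] - blk$start
        if (is.null(blk$refcols)) {
            c1 <- off1; c2 <- off2
        } else {
            c1 <- blk$refcols[off1]; c2 <- blk$refcols[off2]
        }
        w <- pdf$ge[rows] - pdf$gs[rows]
        refGapless <- (c2 - c1 + 1L) == w
        refsub <- substring(blk$texts[[index@reference]], c1, c2)
        refMatch <- refGapless & (refsub == pdf$expected[rows])
        refok[pdf$site[rows]] <- refok[pdf$site[rows]] & refMatch
        for (sp in blk$species) {
            sub <- substring(blk$texts[[sp]], c1, c2)
            good <- refGapless & (sub == pdf$expected[rows]) &
                !grepl("-", sub, fixed = TRUE)
            ## aggregate over pieces: a site is intact in a species only
            ## if every piece is
            si <- pdf$site[rows]
            cur <- intact[cbind(si, match(sp, allSpecies))]
            agg <- ifelse(is.na(cur), good, cur & good)
            intact[cbind(si, match(sp, allSpecies))] <- agg
        }
    }
    ## any piece uncovered, or species missing from a covering block,
    ## leaves NA; sites with uncovered pieces are unalignable
    intact[!covered, ] <- NA
    if (config@absentCountsAgainst) {
        obs <- intact
        obs[is.na(obs)] <- FALSE
        obs[!covered, ] <- NA
        intact <- obs
    }

    clade <- index@clades$clade[match(allSpecies, index@clades$species)]
    isRef <- allSpecies == index@reference
    groups <- list(primate = which(clade == "primate" & !isRef),
                   mammal = which(clade == "mammal"),
                   vertebrate = which(clade == "vertebrate"))
    fracs <- vapply(groups, function(g) {
        if (length(g) == 0) return(rep(NaN, n))
        rowMeans(intact[, g, drop = FALSE], na.rm = TRUE)
    }, numeric(n))
    if (n == 1) fracs <- matrix(fracs, nrow = 1,
                                dimnames = list(NULL, names(groups)))

    pass <- !is.na(fracs) & !is.nan(fracs) & fracs >= config@minFraction
    tier <- rep("none", n)
    base <- if (config@requireReference) refok & covered else covered
    tier[base & pass[, "primate"]] <- "primate"
    tier[base & pass[, "primate"] & pass[, "mammal"]] <- "mammal"
    tier[base & pass[, "primate"] & pass[, "mammal"] &
         pass[, "vertebrate"]] <- "vertebrate"

    sites$tier <- tier
    sites$frac_primate <- fracs[, "primate"]
    sites$frac_mammal <- fracs[, "mammal"]
    sites$frac_vertebrate <- fracs[, "vertebrate"]
    sites$n_species_intact <- rowSums(intact[, !isRef, drop = FALSE],
                                      na.rm = TRUE) +
        as.integer(refok & covered)
    attr(sites, "pieces") <- pieces
    sites
}

#' Stratify sites by conservation tier and site type
#'
#' Builds cumulative stratum counts: a site with tier \code{mammal}
#' contributes to the primate AND mammal strata; counts are therefore
#' monotone non-increasing with stringency. The full grid is returned,
#' including zero strata.
#'
#' @param sites a site table with conservation calls.
#' @param tiers tiers to report (default primate, mammal, vertebrate).
#' @param siteTypes site types to report (default all three).
#' @param by optional column name to stratify by in addition (e.g.
#'   \code{set_id}); its levels can be supplied via \code{byLevels} to
#'   force zero rows for absent groups.
#' @param byLevels values of \code{by} to include.
#' @return data.frame with columns \code{by} (if given), \code{tier},
#'   \code{site_type}, \code{count}.
#' @export
stratifySites <- function(sites, tiers = CLADE_LEVELS,
                          siteTypes = SITE_TYPES,
                          by = NULL, byLevels = NULL) {
    if (!is.null(by)) {
        if (is.null(byLevels)) byLevels <- unique(sites[[by]])
        grid <- expand.grid(g = byLevels, tier = tiers,
                            site_type = siteTypes,
                            stringsAsFactors = FALSE)
    } else {
        grid <- expand.grid(tier = tiers, site_type = siteTypes,
                            stringsAsFactors = FALSE)
    }
    rk <- .tierRank(sites$tier)
    grid$count <- vapply(seq_len(nrow(grid)), function(i) {
        sel <- rk >= .tierRank(grid$tier[i]) &
            sites$site_type == grid$site_type[i]
        if (!is.null(by)) sel <- sel & sites[[by]] == grid$g[i]
        sum(sel)
    }, numeric(1))
    if (!is.null(by)) names(grid)[1] <- by
    grid
}
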