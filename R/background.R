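#' @include AllClasses.R seeds.R conservation.R
NULL

#' Fit a first-order dinucleotide model to a seed pool
#'
#' The initial distribution is the empirical distribution of
#' position-1 nucleotides; the 4x4 transition matrix pools the
#' dinucleotide transitions of all seeds over positions 1-6, with
#' add-one smoothing so that no transition has probability zero.
#'
#' @param seeds character vector of 7-nt RNA seeds.
#' @return A \linkS4class{DinucModel}.
#' @export
fitDinucModel <- function(seeds) {
    if (length(seeds) == 0) .stopf("cannot fit a dinucleotide model to 0 seeds")
    seeds <- .dnaToRna(seeds)
    if (any(nchar(seeds) != 7L) || any(grepl("[^ACGU]", seeds)))
        .stopf("seeds must be 7-nt strings over A/C/G/U")
    chars <- do.call(rbind, strsplit(seeds, "", fixed = TRUE))
    init <- table(factor(chars[, 1], levels = RNA_ALPHABET))
    initial <- as.numeric(init) / sum(init)
    names(initial) <- RNA_ALPHABET
    trans <- matrix(1, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
    for (k in 1:6) {
        t2 <- table(factor(chars[, k], levels = RNA_ALPHABET),
                    factor(chars[, k + 1], levels = RNA_ALPHABET))
        trans <- trans + unclass(t2)
    }
    trans <- matrix(trans / rowSums(trans), 4, 4,
                    dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
    new("DinucModel", initial = initial, transition = trans)
}

#' Sample random seed sets from a dinucleotide model
#'
#' Draws each seed as a 7-step Markov chain from the model. Seeds
#' identical to any real seed are rejected and redrawn, so that the
#' null never absorbs true signal; duplicates within a set are
#' allowed. Fully reproducible given \code{rngSeed}.
#'
#' @param model a \linkS4class{DinucModel}.
#' @param nSets number of random sets (default 20).
#' @param setSize seeds per set (use the real conserved family count).
#' @param realSeeds seeds to reject (RNA strings); set
#'   \code{character(0)} to disable rejection.
#' @param rngSeed integer seed.
#' @param maxDraws rejection-sampling budget before declaring the
#'   model degenerate.
#' @return data.frame with columns \code{set_index}, \code{family}
#'   (synthetic names), \code{seed}.
#' @export
sampleSeedSets <- function(model, nSets = 20L, setSize, realSeeds,
                           rngSeed = 1L, maxDraws = 1e6) {
    if (setSize < 1) .stopf("setSize must be >= 1")
    realSeeds <- .dnaToRna(realSeeds)
    set.seed(rngSeed)
    total <- nSets * setSize
    out <- character(total)
    draws <- 0L
    for (i in seq_len(total)) {
        repeat {
            draws <- draws + 1L
            if (draws > maxDraws)
                .stopf("rejection sampling exceeded %g draws; model degenerate",
                       maxDraws)
            s <- character(7)
            s[1] <- sample(RNA_ALPHABET, 1L, prob = model@initial)
            for (k in 2:7)
                s[k] <- sample(RNA_ALPHABET, 1L,
                               prob = model@transition[s[k - 1], ])
            s <- paste0(s, collapse = "")
            if (!(s %in% realSeeds)) break
        }
        out[i] <- s
    }
    data.frame(
        set_index = rep(seq_len(nSets), each = setSize),
        family = sprintf("rnd%02d_%03d", rep(seq_len(nSets), each = setSize),
                         rep(seq_len(setSize), nSets)),
        seed = out,
        stringsAsFactors = FALSE)
}

## shared scan -> conserve path used for both the real families and the
## random seed sets; returns the finished, conservation-called site table
.mapAndConserve <- function(models, patterns, mafIndex, config) {
    sites <- .scanPatterns(models@sequences, patterns)
    sites <- .finishSites(sites, models)
    callSiteConservation(sites, mafIndex, config)
}

#' Expected stratum counts from random seed sets
#'
#' Runs the random seed sets through exactly the same scan and
#' conservation path as the real seeds, and returns cumulative
#' per-set stratum counts. Feeding the real seed set in as a single
#' "random" set therefore reproduces the observed counts exactly.
#'
#' @param seedSets data.frame from \code{\link{sampleSeedSets}}.
#' @param models a \linkS4class{TranscriptModels} (already subset to
#'   the transcripts under analysis).
#' @param mafIndex a \linkS4class{MafIndex}.
#' @param config a \linkS4class{ConservationConfig}.
#' @param region optional region filter (e.g. "UTR3" or "CDS"): only
#'   sites in that region are counted.
#' @return data.frame with columns \code{set_index}, \code{tier},
#'   \code{site_type}, \code{count} (all strata present, zeros kept).
#' @export
expectedCounts <- function(seedSets, models, mafIndex,
                           config = consConfig(), region = NULL) {
    patterns <- .patternTable(seedSets$family, seedSets$seed,
                              set_id = as.character(seedSets$set_index))
    sites <- .mapAndConserve(models, patterns, mafIndex, config)
    if (!is.null(region)) sites <- sites[sites$region %in% region, ,
                                         drop = FALSE]
    counts <- stratifySites(sites, by = "set_id",
                            byLevels = as.character(unique(seedSets$set_index)))
    names(counts)[1] <- "set_index"
    counts$set_index <- as.integer(counts$set_index)
    counts[order(counts$set_index, match(counts$tier, CLADE_LEVELS),
                 match(counts$site_type, SITE_TYPES)), , drop = FALSE]
}
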