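# Independent brute-force site scanner used as the oracle for the
# Biostrings-based implementation. Everything here is computed with
# plain base R string handling.

oracleRevcomp <- function(x) {
    comp <- chartr("ACGTU", "TGCAA", toupper(x))
    vapply(strsplit(comp, ""), function(ch)
        paste(rev(ch), collapse = ""), character(1))
}

oraclePatterns <- function(seed) {
    m8 <- oracleRevcomp(seed)
    c("8mer" = paste0(m8, "A"),
      "7mer-m8" = m8,
      "7mer-A1" = paste0(oracleRevcomp(substr(seed, 1, 6)), "A"))
}

# position-by-position scan of every pattern over every sequence,
# followed by the documented per-locus suppression rule
oracleScan <- function(seqs, famTab) {
    out <- list()
    for (fi in seq_len(nrow(famTab))) {
        pats <- oraclePatterns(famTab$seed[fi])
        for (si in seq_along(seqs)) {
            s <- seqs[si]
            hits <- list()
            for (ty in names(pats)) {
                p <- pats[[ty]]
                w <- nchar(p)
                n <- nchar(s) - w + 1
                if (n < 1) next
                for (pos in seq_len(n)) {
                    if (substr(s, pos, pos + w - 1) == p)
                        hits[[length(hits) + 1]] <-
                            data.frame(site_type = ty, start = pos - 1L)
                }
            }
            if (length(hits) == 0) next
            h <- do.call(rbind, hits)
            p8 <- h$start[h$site_type == "8mer"]
            keep <- !((h$site_type == "7mer-m8" & h$start %in% p8) |
                      (h$site_type == "7mer-A1" & (h$start - 1L) %in% p8))
            h <- h[keep, , drop = FALSE]
            # best type per locus
            pri <- match(h$site_type, c("8mer", "7mer-m8", "7mer-A1"))
            h <- h[order(h$start, pri), , drop = FALSE]
            h <- h[!duplicated(h$start), , drop = FALSE]
            if (nrow(h) > 0) {
                h$family <- famTab$family[fi]
                h$seq_idx <- si
                out[[length(out) + 1]] <- h
            }
        }
    }
    if (length(out) == 0)
        return(data.frame(site_type = character(0), start = integer(0),
                          family = character(0), seq_idx = integer(0)))
    res <- do.call(rbind, out)
    res[order(res$family, res$seq_idx, res$start), c("family", "seq_idx",
                                                     "start", "site_type")]
}

randomDnaSeqs <- function(n, len, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i)
        paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = ""), character(1))
}

randomRnaSeeds <- function(n, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i)
        paste0(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
               collapse = ""), character(1))
}
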