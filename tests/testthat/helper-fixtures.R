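# shared fixtures, all generated in code

BASES <- c("A", "C", "G", "T")

rseq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# substitute bases at given 1-based positions (cycling to a different base)
substituteAt <- function(s, pos) {
    chars <- strsplit(s, "")[[1]]
    nxt <- c(A = "C", C = "G", G = "T", T = "A")
    chars[pos] <- nxt[chars[pos]]
    paste(chars, collapse = "")
}

# full Smith-Waterman oracle via Biostrings (linear gap -3, match +1,
# mismatch -2), independent of the package aligner
swOracle <- function(query, target) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
        mismatch = -2, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(query, target, type = "local",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 3)
    list(score = Biostrings::score(pa),
        identity = Biostrings::pid(pa, type = "PID1"),
        aligned_length = Biostrings::nchar(pa))
}

smallSignalMatrix <- function(values, condition = c("infected",
        "infected", "uninfected", "uninfected"), is_control = NULL) {
    if (is.null(is_control)) is_control <- rep(FALSE, nrow(values))
    SignalMatrix(values, condition, c(1L, 2L, 1L, 2L), is_control)
}

# naive running-sum oracle: literal position-by-position recomputation,
# independent of the package's streaming implementation
naiveES <- function(stat, members, weight = 1) {
    ord <- order(-stat, names(stat))
    ranked <- stat[ord]
    hit <- names(ranked) %in% members
    nr <- sum(abs(ranked[hit])^weight)
    miss <- 1 / (length(ranked) - sum(hit))
    rs <- 0; best <- 0; bestPos <- 0
    for (i in seq_along(ranked)) {
        rs <- rs + if (hit[i]) abs(ranked[i])^weight / nr else -miss
        if (abs(rs) > abs(best)) { best <- rs; bestPos <- i }
    }
    list(es = unname(best), pos = bestPos)
}

# hand-built probe panel rows
probeRow <- function(probe_id, transcript_id, strand, start, sequence,
        is_control = FALSE)
    data.frame(probe_id = probe_id, transcript_id = transcript_id,
        strand = strand, start = start, length = nchar(sequence),
        sequence = sequence, is_control = is_control)
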