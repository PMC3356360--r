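#' Best local alignment of two nucleotide sequences
#'
#' Deterministic BLASTN-style comparison used throughout the package for
#' assembly reconciliation, cross-hybridization screening and read mapping.
#' Exact k-mer seeds are collected on both strands, seeds are clustered by
#' diagonal, and each cluster is extended by banded Smith-Waterman
#' (match +1, mismatch -2, gap -3 by default, band 32). Identity is
#' 100 * matches / alignment columns, with gap columns counted in the
#' denominator, matching BLAST HSP conventions. N is treated as a mismatch.
#'
#' @param query,target Nucleotide strings (or length-1 DNAStringSet). Both
#'   must be at least \code{minSeed} long.
#' @param minSeed Seed k-mer length (exact matches only).
#' @param band Half-width of the extension band around seed diagonals.
#' @param match,mismatch,gap Alignment scores (gap is linear per column).
#' @param minScore Hits scoring below this are reported as no-match.
#' @return A one-row data.frame (a match record) with columns
#'   \code{query_id}, \code{target_id}, \code{identity},
#'   \code{aligned_length}, \code{strand}, \code{qstart}, \code{qend},
#'   \code{tstart}, \code{tend} (1-based inclusive), \code{score},
#'   \code{matched}; or the same shape with \code{matched = FALSE} and NA
#'   fields when no alignment reaches \code{minScore}.
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
#'     collapse = "")
#' alignPairwise(s, s)$identity  # 100
#' @export
alignPairwise <- function(query, target, minSeed = 15L, band = 32L,
        match = 1L, mismatch = -2L, gap = -3L, minScore = 30L) {
    query <- as.character(query)[1L]
    target <- as.character(target)[1L]
    if (nchar(query) < minSeed || nchar(target) < minSeed)
        stop("both sequences must be at least minSeed (", minSeed,
            ") bases long")
    r <- .cpp_align_pair(toupper(query), toupper(target),
        as.integer(minSeed), as.integer(band), as.integer(match),
        as.integer(mismatch), as.integer(gap), as.integer(minScore))
    if (!r$matched)
        return(data.frame(query_id = NA_character_,
            target_id = NA_character_, identity = NA_real_,
            aligned_length = NA_integer_, strand = NA_character_,
            qstart = NA_integer_, qend = NA_integer_,
            tstart = NA_integer_, tend = NA_integer_,
            score = NA_integer_, matched = FALSE))
    data.frame(query_id = "query", target_id = "target",
        identity = r$identity, aligned_length = r$aligned_length,
        strand = r$strand, qstart = r$qstart, qend = r$qend,
        tstart = r$tstart, tend = r$tend, score = r$score, matched = TRUE)
}

#' Best match of every query contig against a target set
#'
#' For each query the single best-scoring local alignment across all targets
#' and both strands is reported (the cross-assembler comparison step). Ties
#' on score break deterministically: higher identity, then longer aligned
#' length, then lexicographically smallest target id.
#'
#' @param querySet,targetSet \linkS4class{ContigSet}s.
#' @param excludeSelf Drop hits where target id equals query id (for
#'   self-comparison QC).
#' @param tieBreak \code{"identity"} (default, see above) or
#'   \code{"position"} (smallest target id, then leftmost target start; the
#'   read-mapping convention).
#' @inheritParams alignPairwise
#' @return data.frame of match records, one row per query, in query order;
#'   unmatched queries have \code{matched = FALSE} and NA fields.
#' @export
findBestMatches <- function(querySet, targetSet, minSeed = 15L, band = 32L,
        match = 1L, mismatch = -2L, gap = -3L, minScore = 30L,
        excludeSelf = FALSE, tieBreak = c("identity", "position")) {
    stopifnot(is(querySet, "ContigSet"), is(targetSet, "ContigSet"))
    if (length(querySet) == 0L || length(targetSet) == 0L)
        stop("query and target sets must be non-empty")
    tieBreak <- match.arg(tieBreak)
    .cpp_best_matches(
        as.character(contigSequences(querySet)), names(querySet),
        as.character(contigSequences(targetSet)), names(targetSet),
        as.integer(minSeed), as.integer(band), as.integer(match),
        as.integer(mismatch), as.integer(gap), as.integer(minScore),
        isTRUE(excludeSelf), if (tieBreak == "identity") 0L else 1L)
}
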