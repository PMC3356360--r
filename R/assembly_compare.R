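#' Classify query contigs as unique or redundant against a target assembly
#'
#' A query is redundant when its best match covers at least
#' \code{minAligned} alignment columns at \code{minIdentity} percent identity
#' or better; otherwise (including no-match) it is unique. This is the
#' decision rule used to pick which secondary-assembly contigs enter the
#' merged transcript set.
#'
#' @param matches data.frame from \code{\link{findBestMatches}}.
#' @param minAligned Minimum alignment length (bp) for redundancy.
#' @param minIdentity Minimum percent identity for redundancy.
#' @return Named character vector, query id -> "unique"/"redundant".
#' @export
classifyUnique <- function(matches, minAligned = 200, minIdentity = 95) {
    redundant <- matches$matched &
        !is.na(matches$aligned_length) &
        matches$aligned_length >= minAligned &
        matches$identity >= minIdentity
    setNames(ifelse(redundant, "redundant", "unique"), matches$query_id)
}

#' Cross-assembler match summary
#'
#' Fraction of queries with any match, plus mean identity and mean aligned
#' length of the matched queries — the reproducibility readout of a
#' two-assembler comparison.
#'
#' @param matches data.frame from \code{\link{findBestMatches}}.
#' @return list with \code{n_queries}, \code{n_matched}, \code{pct_matched}
#'   (percent, half-up to 1 decimal), \code{mean_identity},
#'   \code{mean_aligned_length} (half-up to 1 decimal).
#' @export
crossMatchSummary <- function(matches) {
    n <- nrow(matches)
    m <- sum(matches$matched)
    list(n_queries = n, n_matched = m,
        pct_matched = roundHalfUp(100 * m / n, 1),
        mean_identity = roundHalfUp(mean(matches$identity[matches$matched]), 1),
        mean_aligned_length =
            roundHalfUp(mean(matches$aligned_length[matches$matched]), 1))
}

#' Merge a primary and a secondary assembly into one non-redundant set
#'
#' Length-filters both assemblies at \code{minLength}, keeps every retained
#' primary contig, classifies each retained secondary contig against the
#' primary set with \code{\link{classifyUnique}}, and adds only the unique
#' ones. Merged ids carry the source label as a prefix when ids collide
#' across sources.
#'
#' @param primary,secondary \linkS4class{ContigSet}s; \code{primary} is the
#'   backbone that is kept in full.
#' @param minLength Contigs shorter than this are removed from both sides.
#' @param minAligned,minIdentity Redundancy thresholds, see
#'   \code{\link{classifyUnique}}.
#' @param matches Optional precomputed \code{\link{findBestMatches}}
#'   (secondary vs primary, after length filtering); computed if NULL.
#' @return list with \code{merged} (\linkS4class{ContigSet}), \code{report}
#'   (see \code{\link{mergeReport}}), \code{classification} (named vector for
#'   the secondary contigs) and \code{matches}.
#' @export
mergeAssemblies <- function(primary, secondary, minLength = 200,
        minAligned = 200, minIdentity = 95, matches = NULL) {
    stopifnot(is(primary, "ContigSet"), is(secondary, "ContigSet"))
    pKeep <- primary[contigLengths(primary) >= minLength]
    sKeep <- secondary[contigLengths(secondary) >= minLength]
    nFiltered <- (length(primary) - length(pKeep)) +
        (length(secondary) - length(sKeep))
    if (is.null(matches))
        matches <- findBestMatches(sKeep, pKeep)
    cls <- classifyUnique(matches, minAligned, minIdentity)
    uniqueIds <- names(cls)[cls == "unique"]
    sAdd <- contigSequences(sKeep)[uniqueIds]
    pSeqs <- contigSequences(pKeep)
    if (any(names(sAdd) %in% names(pSeqs)))
        names(sAdd) <- paste(sourceLabel(secondary), names(sAdd), sep = "_")
    merged <- ContigSet(c(pSeqs, sAdd),
        paste(sourceLabel(primary), sourceLabel(secondary), sep = "+"))
    report <- mergeReport(
        n_primary_retained = length(pKeep),
        n_secondary_unique_added = length(sAdd),
        pct_secondary_matched = roundHalfUp(
            100 * sum(matches$matched) / nrow(matches), 1),
        mean_identity = roundHalfUp(
            mean(matches$identity[matches$matched]), 1),
        mean_aligned_length = roundHalfUp(
            mean(matches$aligned_length[matches$matched]), 1),
        min_length_filtered = nFiltered)
    list(merged = merged, report = report, classification = cls,
        matches = matches)
}

#' Merge accounting report
#'
#' Assembles the bookkeeping of a two-assembly merge; \code{n_final} is
#' always \code{n_primary_retained + n_secondary_unique_added}. Counts may
#' also be supplied directly, e.g. to recompute a published merge total from
#' its printed inputs.
#'
#' @param n_primary_retained,n_secondary_unique_added Contig counts.
#' @param pct_primary_matched,pct_secondary_matched Percent of each
#'   assembly's contigs with a cross-assembly match (optional).
#' @param mean_identity,mean_aligned_length Summary of the matched pairs
#'   (optional).
#' @param min_length_filtered Contigs removed by the length filter.
#' @return list of class \code{mergeReport} including \code{n_final}.
#' @examples
#' mergeReport(23682, 5904)$n_final  # 29586
#' @export
mergeReport <- function(n_primary_retained, n_secondary_unique_added,
        pct_primary_matched = NA_real_, pct_secondary_matched = NA_real_,
        mean_identity = NA_real_, mean_aligned_length = NA_real_,
        min_length_filtered = 0L) {
    stopifnot(n_primary_retained >= 0, n_secondary_unique_added >= 0)
    structure(list(
        n_primary_retained = n_primary_retained,
        n_secondary_unique_added = n_secondary_unique_added,
        n_final = n_primary_retained + n_secondary_unique_added,
        pct_primary_matched = pct_primary_matched,
        pct_secondary_matched = pct_secondary_matched,
        mean_identity = mean_identity,
        mean_aligned_length = mean_aligned_length,
        min_length_filtered = min_length_filtered),
        class = "mergeReport")
}

#' Length statistics and histogram for an assembly
#'
#' @param x A \linkS4class{ContigSet}.
#' @param bins Length bin edges for the histogram (bp); right-closed,
#'   values beyond the last edge are counted in an overflow bin.
#' @return list with \code{n}, \code{mean_length} (half-up, 1 decimal),
#'   \code{n50}, \code{total_bp} and \code{histogram} (named counts). N50 is
#'   the length of the smallest contig in the minimal set of longest contigs
#'   covering at least half the total bases.
#' @export
assemblyStats <- function(x, bins = c(0, 500, 1000, 2000, 4000, 8000)) {
    stopifnot(is(x, "ContigSet"))
    w <- unname(contigLengths(x))
    if (length(w) == 0L)
        return(list(n = 0L, mean_length = 0, n50 = 0L, total_bp = 0L,
            histogram = integer(0)))
    sw <- sort(w, decreasing = TRUE)
    n50 <- sw[which(cumsum(sw) >= sum(sw) / 2)[1L]]
    edges <- c(bins, Inf)
    h <- table(cut(w, breaks = edges, right = TRUE, include.lowest = TRUE))
    list(n = length(w), mean_length = roundHalfUp(mean(w), 1), n50 = n50,
        total_bp = sum(w), histogram = setNames(as.integer(h), names(h)))
}

#' Map reads to a reference contig set
#'
#' Each read is aligned with the package aligner; a read counts toward its
#' single best-scoring reference position iff its aligned query span is at
#' least \code{minLenFrac} of the read length and identity is at least
#' \code{minId}. Ties on score break toward the smallest reference id, then
#' the leftmost position. Multi-mapping reads are never counted twice.
#'
#' @param reads \linkS4class{ContigSet} (or named DNAStringSet) of reads.
#' @param refSet Reference \linkS4class{ContigSet}.
#' @param minLenFrac Minimum aligned fraction of the read length.
#' @param minId Minimum identity as a fraction (0.90 = 90\%).
#' @inheritParams alignPairwise
#' @return list with \code{counts} (named per-contig read counts over all
#'   reference contigs), \code{mapped} (logical per read), \code{hits} (match
#'   records of the mapped reads) and \code{aligned_bases} (per-contig summed
#'   aligned target bases, the numerator of per-base depth).
#' @export
mapReads <- function(reads, refSet, minLenFrac = 0.95, minId = 0.90,
        minSeed = 15L, minScore = 30L) {
    if (!is(reads, "ContigSet")) reads <- ContigSet(reads, "reads")
    stopifnot(is(refSet, "ContigSet"))
    m <- findBestMatches(reads, refSet, minSeed = minSeed,
        minScore = minScore, tieBreak = "position")
    rl <- unname(contigLengths(reads))
    qspan <- m$qend - m$qstart + 1L
    ok <- m$matched & !is.na(qspan) & qspan >= minLenFrac * rl &
        m$identity >= 100 * minId
    hits <- m[ok, , drop = FALSE]
    counts <- setNames(integer(length(refSet)), names(refSet))
    tb <- table(hits$target_id)
    counts[names(tb)] <- as.integer(tb)
    ab <- setNames(numeric(length(refSet)), names(refSet))
    if (nrow(hits)) {
        sp <- tapply(hits$tend - hits$tstart + 1L, hits$target_id, sum)
        ab[names(sp)] <- as.numeric(sp)
    }
    list(counts = counts, mapped = ok, hits = hits, aligned_bases = ab)
}

#' Coverage summary from read counts
#'
#' Mean fold coverage is \code{mean reads per contig * read length / mean
#' contig length}, reported truncated to one decimal (651.7 reads of 100 bp
#' on 1,009 bp contigs gives 64.5x). Per-contig mean per-base depth uses
#' summed aligned bases when supplied, else \code{count * read_length /
#' length}.
#'
#' @param counts Named per-contig read counts (keyed by \code{refSet} ids).
#' @param readLength Read length in bp.
#' @param refSet Reference \linkS4class{ContigSet}.
#' @param alignedBases Optional named per-contig summed aligned bases.
#' @return list of class \code{coverageSummary}: \code{mapped_reads},
#'   \code{mean_reads_per_contig}, \code{read_length},
#'   \code{mean_contig_length}, \code{mean_fold_coverage} (truncated to one
#'   decimal), \code{per_contig_depth}.
#' @examples
#' ref <- ContigSet(setNames(strrep("ACGT", 252:253), c("a", "b")), "toy")
#' # printed-report arithmetic: 651.7 * 100 / 1009 -> 64.5
#' @export
coverageSummary <- function(counts, readLength, refSet,
        alignedBases = NULL) {
    stopifnot(is(refSet, "ContigSet"))
    if (length(refSet) == 0L) stop("empty reference set")
    if (!all(names(counts) %in% names(refSet)))
        stop("counts keyed by ids absent from the reference set")
    full <- setNames(numeric(length(refSet)), names(refSet))
    full[names(counts)] <- counts
    lens <- contigLengths(refSet)
    meanLen <- mean(lens)
    meanReads <- mean(full)
    depth <- if (!is.null(alignedBases)) {
        ab <- setNames(numeric(length(refSet)), names(refSet))
        ab[names(alignedBases)] <- alignedBases
        ab / lens
    } else full * readLength / lens
    structure(list(
        mapped_reads = sum(full),
        mean_reads_per_contig = meanReads,
        read_length = readLength,
        mean_contig_length = meanLen,
        mean_fold_coverage = truncDecimal(meanReads * readLength / meanLen, 1),
        per_contig_depth = depth), class = "coverageSummary")
}

#' Fold coverage from printed summary numbers
#'
#' The one-line coverage arithmetic used in assembly reports:
#' \code{meanReads * readLength / meanLength}, truncated to one decimal.
#'
#' @param meanReads Mean mapped reads per contig.
#' @param readLength Read length (bp).
#' @param meanLength Mean contig length (bp).
#' @return Fold coverage, truncated to one decimal.
#' @examples
#' foldCoverage(651.7, 100, 1009)  # 64.5
#' @export
foldCoverage <- function(meanReads, readLength, meanLength)
    truncDecimal(meanReads * readLength / meanLength, 1)
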