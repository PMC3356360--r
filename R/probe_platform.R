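#' Design strand-paired oligonucleotide probes for a transcript set
#'
#' For every transcript long enough to host them, draws \code{nPerStrand}
#' distinct 60-mer start offsets per strand (uniformly, without
#' replacement). Sense (\code{+}) probes are transcript substrings;
#' antisense (\code{-}) probes are reverse complements of substrings.
#' Random negative-control probes provide the background distribution used
#' by WABS filtering. Deterministic under \code{seed}.
#'
#' @param transcripts A named \link[Biostrings]{DNAStringSet},
#'   \linkS4class{ContigSet}, or \code{TruthTranscriptome}.
#' @param nPerStrand Probes per strand per transcript.
#' @param probeLen Probe length in bp (Agilent-style 60-mers).
#' @param nControls Number of random negative-control probes.
#' @param seed Integer seed for offset draws.
#' @return A \linkS4class{ProbePanel}. Transcripts shorter than
#'   \code{probeLen + nPerStrand - 1} are skipped with a warning.
#' @export
designProbes <- function(transcripts, nPerStrand = 3L, probeLen = 60L,
        nControls = 100L, seed = 1L) {
    if (inherits(transcripts, "TruthTranscriptome"))
        transcripts <- transcripts$sequences
    if (is(transcripts, "ContigSet"))
        transcripts <- contigSequences(transcripts)
    stopifnot(is(transcripts, "DNAStringSet"))
    withSeed(seed, {
        lens <- Biostrings::width(transcripts)
        ok <- lens >= probeLen + nPerStrand - 1L
        if (any(!ok))
            warning(sum(!ok), " transcript(s) shorter than ",
                probeLen + nPerStrand - 1L, " bp skipped in probe design")
        rows <- vector("list", sum(ok) + 1L)
        k <- 0L
        for (i in which(ok)) {
            tid <- names(transcripts)[i]
            npos <- lens[i] - probeLen + 1L
            for (strand in c("+", "-")) {
                starts <- sort(sample.int(npos, nPerStrand)) - 1L
                sub <- substring(as.character(transcripts[[i]]),
                    starts + 1L, starts + probeLen)
                if (strand == "-")
                    sub <- as.character(Biostrings::reverseComplement(
                        Biostrings::DNAStringSet(sub)))
                k <- k + 1L
                rows[[k]] <- data.frame(
                    probe_id = sprintf("%s_%s%d", tid,
                        if (strand == "+") "p" else "m",
                        seq_len(nPerStrand)),
                    transcript_id = tid, strand = strand,
                    start = starts, length = probeLen, sequence = sub,
                    is_control = FALSE)
            }
        }
        if (nControls > 0L) {
            k <- k + 1L
            rows[[k]] <- data.frame(
                probe_id = sprintf("CTRL%04d", seq_len(nControls)),
                transcript_id = NA_character_, strand = "+",
                start = -1L, length = probeLen,
                sequence = randomSequence(rep(probeLen, nControls)),
                is_control = TRUE)
        }
        ProbePanel(do.call(rbind, rows[seq_len(k)]))
    })
}

#' Screen probes for potential cross-hybridization
#'
#' A probe is removed when the aligner finds a local hit on any non-parent
#' transcript with identity at least \code{maxOfftargetIdentity} percent
#' over at least \code{minOfftargetSpan} alignment columns (either strand).
#' Control probes are never screened.
#'
#' @param panel A \linkS4class{ProbePanel}.
#' @param transcripts The transcript set the probes were designed on.
#' @param maxOfftargetIdentity Identity threshold (percent) for removal.
#' @param minOfftargetSpan Minimum off-target alignment columns for removal.
#' @param minSeed Seed k-mer length of the aligner.
#' @return list with \code{panel} (filtered \linkS4class{ProbePanel}) and
#'   \code{removed} (data.frame probe_id, transcript_id, offtarget_id).
#' @export
screenCrossHybridization <- function(panel, transcripts,
        maxOfftargetIdentity = 90, minOfftargetSpan = 45, minSeed = 15L) {
    if (inherits(transcripts, "TruthTranscriptome"))
        transcripts <- transcripts$sequences
    if (is(transcripts, "ContigSet"))
        transcripts <- contigSequences(transcripts)
    probes <- probeTable(panel)
    tg <- probes[!probes$is_control, , drop = FALSE]
    if (nrow(tg) == 0L)
        return(list(panel = panel,
            removed = data.frame(probe_id = character(),
                transcript_id = character(), offtarget_id = character())))
    off <- .cpp_offtarget(tg$sequence, tg$transcript_id,
        as.character(transcripts), names(transcripts),
        as.integer(minSeed), 32L, 1L, -2L, -3L,
        as.numeric(maxOfftargetIdentity), as.integer(minOfftargetSpan))
    drop <- !is.na(off)
    removed <- data.frame(probe_id = tg$probe_id[drop],
        transcript_id = tg$transcript_id[drop],
        offtarget_id = off[drop])
    keep <- !(probes$probe_id %in% removed$probe_id)
    list(panel = ProbePanel(probes[keep, , drop = FALSE]), removed = removed)
}

backgroundStats <- function(signal) {
    v <- intensities(signal)
    ctl <- isControlProbe(signal)
    if (!any(ctl))
        stop("no negative-control probes in the signal matrix; supply ",
            "explicit background statistics via 'background'")
    data.frame(sample_id = colnames(v),
        mean = colMeans(v[ctl, , drop = FALSE]),
        sd = apply(v[ctl, , drop = FALSE], 2, sd))
}

#' Well-above-background (WABS) flags
#'
#' A probe has WABS in a sample when its linear-scale intensity exceeds the
#' sample's background mean plus \code{kSigma} background SDs, background
#' statistics coming from the negative-control probes of that sample. At
#' transcript level, \code{wabs_all_samples} requires at least one probe
#' with WABS in every sample, and \code{wabs_three_one_direction} requires
#' all three probes of at least one strand to have WABS in every sample
#' (strands that lost probes to screening are not eligible for the
#' three-probe flag).
#'
#' @param signal A \linkS4class{SignalMatrix}.
#' @param panel A \linkS4class{ProbePanel} (maps probes to transcripts and
#'   strands); probes absent from the signal matrix are ignored.
#' @param kSigma Background SD multiplier.
#' @param background Optional data.frame (sample_id, mean, sd) overriding
#'   control-probe statistics; required when the matrix has no controls.
#' @param nPerStrand Full probe complement per strand (for the three-probe
#'   flag).
#' @return list with \code{probeWabs} (logical probe x sample matrix over
#'   non-control probes), \code{background}, and \code{transcripts}
#'   (data.frame: transcript_id, wabs_all_samples,
#'   wabs_three_one_direction).
#' @export
wabsFlags <- function(signal, panel, kSigma = 3, background = NULL,
        nPerStrand = 3L) {
    stopifnot(is(signal, "SignalMatrix"), is(panel, "ProbePanel"))
    if (is.null(background)) background <- backgroundStats(signal)
    v <- intensities(signal)
    stopifnot(all(background$sample_id == colnames(v)))
    thr <- background$mean + kSigma * background$sd
    tg <- targetProbes(panel)
    tg <- tg[tg$probe_id %in% rownames(v), , drop = FALSE]
    pv <- v[tg$probe_id, , drop = FALSE]
    wabs <- sweep(pv, 2, thr, ">")
    allS <- rowSums(wabs) == ncol(wabs)   # probe WABS in every sample
    byT <- split(seq_len(nrow(tg)), tg$transcript_id)
    res <- lapply(byT, function(ix) {
        anyAll <- any(allS[ix])
        three <- FALSE
        for (s in c("+", "-")) {
            sx <- ix[tg$strand[ix] == s]
            if (length(sx) == nPerStrand && all(allS[sx])) three <- TRUE
        }
        c(anyAll, three)
    })
    m <- do.call(rbind, res)
    list(probeWabs = wabs, background = background,
        transcripts = data.frame(transcript_id = names(byT),
            wabs_all_samples = m[, 1], wabs_three_one_direction = m[, 2],
            row.names = NULL))
}

#' Infer transcript orientation from strand-wise cumulative probe signal
#'
#' For each transcript, sums linear-scale intensities of the surviving
#' probes of each strand across all samples; the chosen strand is the one
#' with the higher cumulative signal, and the best probe is the chosen
#' strand's probe with the highest summed intensity. Ties break toward the
#' strand with the higher single-probe maximum, then toward the
#' lexicographically smallest probe id. Transcripts lacking surviving probes
#' on either strand are called \code{undetermined}.
#'
#' @param signal A \linkS4class{SignalMatrix}.
#' @param panel A \linkS4class{ProbePanel} (post-screening).
#' @return data.frame with one row per transcript: \code{transcript_id},
#'   \code{chosen_strand} ("+", "-" or "undetermined"),
#'   \code{cum_signal_plus}, \code{cum_signal_minus}, \code{best_probe_id}.
#' @export
inferOrientation <- function(signal, panel) {
    stopifnot(is(signal, "SignalMatrix"), is(panel, "ProbePanel"))
    v <- intensities(signal)
    tg <- targetProbes(panel)
    tg <- tg[tg$probe_id %in% rownames(v), , drop = FALSE]
    tot <- rowSums(v[tg$probe_id, , drop = FALSE])
    byT <- split(seq_len(nrow(tg)), tg$transcript_id)
    rows <- lapply(names(byT), function(tid) {
        ix <- byT[[tid]]
        plus <- ix[tg$strand[ix] == "+"]
        minus <- ix[tg$strand[ix] == "-"]
        cp <- sum(tot[plus]); cm <- sum(tot[minus])
        if (length(plus) == 0L || length(minus) == 0L)
            return(data.frame(transcript_id = tid,
                chosen_strand = "undetermined", cum_signal_plus = cp,
                cum_signal_minus = cm, best_probe_id = NA_character_))
        chosen <- if (cp > cm) "+" else if (cm > cp) "-"
            else if (max(tot[plus]) > max(tot[minus])) "+"
            else if (max(tot[minus]) > max(tot[plus])) "-"
            else if (min(tg$probe_id[plus]) <= min(tg$probe_id[minus]))
                "+" else "-"
        cand <- if (chosen == "+") plus else minus
        best <- cand[order(-tot[cand], tg$probe_id[cand])][1L]
        data.frame(transcript_id = tid, chosen_strand = chosen,
            cum_signal_plus = cp, cum_signal_minus = cm,
            best_probe_id = tg$probe_id[best])
    })
    do.call(rbind, rows)
}

#' Percent of a count over a total, printed-report style
#'
#' Half-up rounding to \code{digits} decimals (27,431 of 27,873 gives 98.4).
#'
#' @param count,total Counts.
#' @param digits Decimals.
#' @return Percentage.
#' @examples
#' percentOf(27431, 27873)  # 98.4
#' @export
percentOf <- function(count, total, digits = 1) {
    if (total == 0) return(NA_real_)
    roundHalfUp(100 * count / total, digits)
}

#' Platform summary report
#'
#' Counts and percentages describing the array platform: sequences with
#' probes on the array, WABS fractions, orientation calls and the final
#' selected probe count. Percentages are half-up to one decimal; the
#' denominator is the number of sequences with probes on the array.
#'
#' @param flags Output of \code{\link{wabsFlags}}.
#' @param calls Output of \code{\link{inferOrientation}}.
#' @param panel The screened \linkS4class{ProbePanel}.
#' @return list with \code{n_on_array}, \code{n_wabs_all},
#'   \code{pct_wabs_all}, \code{n_wabs_three_one_direction},
#'   \code{pct_wabs_three_one_direction}, \code{n_oriented},
#'   \code{n_selected_probes}.
#' @export
platformReport <- function(flags, calls, panel) {
    n <- length(unique(targetProbes(panel)$transcript_id))
    nAll <- sum(flags$transcripts$wabs_all_samples)
    nThree <- sum(flags$transcripts$wabs_three_one_direction)
    det <- calls$chosen_strand != "undetermined"
    list(n_on_array = n,
        n_wabs_all = nAll, pct_wabs_all = percentOf(nAll, n),
        n_wabs_three_one_direction = nThree,
        pct_wabs_three_one_direction = percentOf(nThree, n),
        n_oriented = sum(det),
        n_selected_probes = sum(!is.na(calls$best_probe_id[det])))
}
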