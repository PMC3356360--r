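#' ContigSet: assembled sequences from one assembler
#'
#' A set of named nucleotide contigs with a provenance label identifying the
#' assembler (or merge) that produced it. Wraps a
#' \link[Biostrings]{DNAStringSet}; ids must be unique, sequences non-empty
#' and over the alphabet A/C/G/T/N.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} of contigs.
#' @slot sourceLabel Single string naming the producing assembler/run.
#' @export
setClass("ContigSet",
    representation(sequences = "DNAStringSet", sourceLabel = "character"))

setValidity("ContigSet", function(object) {
    seqs <- object@sequences
    msg <- character()
    if (length(object@sourceLabel) != 1L || is.na(object@sourceLabel))
        msg <- c(msg, "sourceLabel must be a single string")
    if (length(seqs)) {
        ids <- names(seqs)
        if (is.null(ids) || anyNA(ids) || any(ids == ""))
            msg <- c(msg, "all contigs must be named")
        else if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicate contig ids (e.g. '%s')",
                ids[duplicated(ids)][1L]))
        w <- Biostrings::width(seqs)
        if (any(w == 0L))
            msg <- c(msg, sprintf("empty sequence for contig '%s'",
                ids[which(w == 0L)[1L]]))
        freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
        bad <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
        if (bad > 0)
            msg <- c(msg, "sequences contain letters outside A/C/G/T/N")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ContigSet
#'
#' @param sequences A named \link[Biostrings]{DNAStringSet} or named character
#'   vector of nucleotide sequences (case-folded to upper).
#' @param sourceLabel Provenance label, e.g. the assembler/run name.
#' @return A \linkS4class{ContigSet}.
#' @examples
#' cs <- ContigSet(c(c1 = "ACGTACGT"), "toy")
#' contigLengths(cs)
#' @export
ContigSet <- function(sequences, sourceLabel = "unknown") {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    new("ContigSet", sequences = sequences,
        sourceLabel = as.character(sourceLabel))
}

#' @describeIn ContigSet Number of contigs.
#' @param x,object A ContigSet.
#' @export
setMethod("length", "ContigSet", function(x) length(x@sequences))

#' @describeIn ContigSet Contig ids.
#' @export
setMethod("names", "ContigSet", function(x) names(x@sequences))

#' Accessors for ContigSet
#'
#' \code{contigSequences} returns the underlying DNAStringSet;
#' \code{sourceLabel} the provenance label; \code{contigLengths} the widths.
#'
#' @param x A \linkS4class{ContigSet}.
#' @return See descriptions.
#' @export
contigSequences <- function(x) x@sequences

#' @rdname contigSequences
#' @export
sourceLabel <- function(x) x@sourceLabel

#' @rdname contigSequences
#' @export
contigLengths <- function(x) setNames(Biostrings::width(x@sequences),
    names(x@sequences))

#' @describeIn ContigSet Subset by index or id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
    ContigSet(x@sequences[i], x@sourceLabel)
})

setMethod("show", "ContigSet", function(object) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("ContigSet '%s': %d contigs", object@sourceLabel,
        length(object)))
    if (length(object))
        cat(sprintf(", width %d..%d (mean %.1f)", min(w), max(w), mean(w)))
    cat("\n")
})

#' ProbePanel: oligonucleotide probe definitions for a transcript set
#'
#' Holds the probe table (probe id, parent transcript, strand, 0-based start
#' offset, length, sequence) plus negative-control background probes used for
#' WABS thresholds. Sense-strand (\code{+}) probes equal the transcript
#' substring; antisense (\code{-}) probes its reverse complement.
#'
#' @slot probes A data.frame with columns \code{probe_id}, \code{transcript_id},
#'   \code{strand}, \code{start}, \code{length}, \code{sequence},
#'   \code{is_control}.
#' @export
setClass("ProbePanel", representation(probes = "data.frame"))

setValidity("ProbePanel", function(object) {
    p <- object@probes
    need <- c("probe_id", "transcript_id", "strand", "start", "length",
        "sequence", "is_control")
    if (!all(need %in% names(p)))
        return(paste("probe table must have columns:",
            paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(p$probe_id)) msg <- c(msg, "duplicate probe ids")
    if (nrow(p) && !all(p$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    if (nrow(p) && any(p$start < 0 & !p$is_control))
        msg <- c(msg, "negative probe offsets")
    if (length(msg)) msg else TRUE
})

#' Construct a ProbePanel from a probe table
#'
#' @param probes data.frame with the columns documented in
#'   \linkS4class{ProbePanel}.
#' @return A \linkS4class{ProbePanel}.
#' @export
ProbePanel <- function(probes) {
    probes$probe_id <- as.character(probes$probe_id)
    probes$transcript_id <- as.character(probes$transcript_id)
    probes$strand <- as.character(probes$strand)
    rownames(probes) <- NULL
    new("ProbePanel", probes = probes)
}

#' @describeIn ProbePanel Number of probes (controls included).
#' @param x,object A ProbePanel.
#' @export
setMethod("length", "ProbePanel", function(x) nrow(x@probes))

#' Accessors for ProbePanel
#'
#' \code{probeTable} returns the full probe data.frame; \code{controlProbes}
#' the ids of negative-control probes; \code{targetProbes} the non-control
#' subtable.
#'
#' @param x A \linkS4class{ProbePanel}.
#' @return See descriptions.
#' @export
probeTable <- function(x) x@probes

#' @rdname probeTable
#' @export
controlProbes <- function(x) x@probes$probe_id[x@probes$is_control]

#' @rdname probeTable
#' @export
targetProbes <- function(x) x@probes[!x@probes$is_control, , drop = FALSE]

setMethod("show", "ProbePanel", function(object) {
    p <- object@probes
    cat(sprintf("ProbePanel: %d probes (%d controls) on %d transcripts\n",
        nrow(p), sum(p$is_control),
        length(unique(p$transcript_id[!p$is_control]))))
})

#' SignalMatrix: probe-level hybridization intensities
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{intensity} (linear scale, strictly positive), probe metadata in
#' \code{rowData} (at least \code{is_control}) and sample metadata in
#' \code{colData} (\code{condition} in \{infected, uninfected\},
#' \code{replicate}).
#'
#' @export
setClass("SignalMatrix", contains = "SummarizedExperiment")

setValidity("SignalMatrix", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        v <- SummarizedExperiment::assay(object, "intensity")
        if (anyNA(v)) msg <- c(msg, "intensities must be complete (no NA)")
        else if (any(v <= 0)) msg <- c(msg, "intensities must be > 0")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("condition", "replicate") %in% names(cd)))
        msg <- c(msg, "colData needs 'condition' and 'replicate'")
    else if (!all(cd$condition %in% c("infected", "uninfected")))
        msg <- c(msg, "condition must be 'infected' or 'uninfected'")
    if (!"is_control" %in%
            names(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData needs logical 'is_control'")
    if (length(msg)) msg else TRUE
})

#' Construct a SignalMatrix
#'
#' @param intensity numeric matrix, probes x samples, linear scale > 0, with
#'   dimnames.
#' @param condition character vector per sample: "infected"/"uninfected".
#' @param replicate integer replicate index per sample.
#' @param is_control logical per probe: negative-control background probe.
#' @return A \linkS4class{SignalMatrix}.
#' @examples
#' m <- matrix(2^rnorm(8, 8), 2, 4,
#'     dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
#' sm <- SignalMatrix(m, rep(c("infected", "uninfected"), each = 2),
#'     c(1, 2, 1, 2), c(FALSE, TRUE))
#' @export
SignalMatrix <- function(intensity, condition, replicate,
        is_control = rep(FALSE, nrow(intensity))) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity),
        colData = S4Vectors::DataFrame(condition = as.character(condition),
            replicate = as.integer(replicate),
            row.names = colnames(intensity)),
        rowData = S4Vectors::DataFrame(is_control = as.logical(is_control),
            row.names = rownames(intensity)))
    new("SignalMatrix", se)
}

#' Accessors for SignalMatrix
#'
#' \code{intensities} returns the linear-scale probe x sample matrix;
#' \code{sampleConditions} the per-sample condition labels;
#' \code{isControlProbe} the per-probe control flag.
#'
#' @param x A \linkS4class{SignalMatrix}.
#' @return See descriptions.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @rdname intensities
#' @export
sampleConditions <- function(x)
    setNames(SummarizedExperiment::colData(x)$condition, colnames(x))

#' @rdname intensities
#' @export
isControlProbe <- function(x)
    setNames(SummarizedExperiment::rowData(x)$is_control, rownames(x))
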