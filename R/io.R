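#' Read a FASTA file into a ContigSet
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are case-folded to upper. Empty records and duplicate ids are
#' explicit errors.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param sourceLabel Provenance label for the resulting set.
#' @return A \linkS4class{ContigSet}.
#' @export
readFasta <- function(path, sourceLabel = basename(path)) {
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    w <- Biostrings::width(seqs)
    if (any(w == 0L))
        stop("empty sequence for record '", names(seqs)[w == 0L][1L],
            "' in ", path)
    if (anyDuplicated(names(seqs)))
        stop("duplicate id '", names(seqs)[duplicated(names(seqs))][1L],
            "' in ", path)
    ContigSet(Biostrings::DNAStringSet(toupper(as.character(seqs))),
        sourceLabel)
}

#' Write a ContigSet (or DNAStringSet) to FASTA
#'
#' Lossless against \code{\link{readFasta}}: id order and sequence content
#' round-trip exactly.
#'
#' @param x A \linkS4class{ContigSet} or named DNAStringSet.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
    if (is(x, "ContigSet")) x <- contigSequences(x)
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
    invisible(path)
}

#' Write reads as FASTQ with a constant placeholder quality
#'
#' @param reads Named DNAStringSet.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
        function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
    invisible(path)
}

#' Read a probe-by-sample signal matrix from TSV
#'
#' Expects a header row of sample ids with a leading \code{probe_id}
#' column; all intensity cells must parse as positive numbers (errors name
#' the offending cell). Sample conditions and replicates come from a
#' metadata table, control flags from the probe panel.
#'
#' @param path Signal TSV (probe_id + one column per sample).
#' @param sampleMeta data.frame (sample_id, condition, replicate) or path
#'   to a TSV with those columns.
#' @param isControl Named logical per probe (e.g. from a
#'   \linkS4class{ProbePanel}); defaults to all FALSE.
#' @return A \linkS4class{SignalMatrix}.
#' @export
readSignalMatrix <- function(path, sampleMeta, isControl = NULL) {
    raw <- read.delim(path, check.names = FALSE,
        colClasses = "character")
    if (names(raw)[1L] != "probe_id")
        stop("first column of ", path, " must be 'probe_id'")
    if (is.character(sampleMeta))
        sampleMeta <- read.delim(sampleMeta, check.names = FALSE)
    need <- c("sample_id", "condition", "replicate")
    if (!all(need %in% names(sampleMeta)))
        stop("sample metadata needs columns: ",
            paste(need, collapse = ", "))
    samples <- names(raw)[-1L]
    missing <- setdiff(samples, sampleMeta$sample_id)
    if (length(missing))
        stop("sample column '", missing[1L],
            "' has no metadata row")
    m <- matrix(NA_real_, nrow(raw), length(samples),
        dimnames = list(raw$probe_id, samples))
    for (j in seq_along(samples)) {
        v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop("non-numeric intensity at row ", bad[1L], " (probe '",
                raw$probe_id[bad[1L]], "'), column '", samples[j], "'")
        m[, j] <- v
    }
    meta <- sampleMeta[match(samples, sampleMeta$sample_id), ]
    ctl <- if (is.null(isControl)) rep(FALSE, nrow(m))
        else unname(isControl[rownames(m)]) %in% TRUE
    SignalMatrix(m, meta$condition, meta$replicate, ctl)
}

#' Write a signal matrix to TSV
#'
#' @param signal A \linkS4class{SignalMatrix}.
#' @param path Output path (probe_id + one column per sample).
#' @return \code{path}, invisibly.
#' @export
writeSignalMatrix <- function(signal, path) {
    v <- intensities(signal)
    df <- data.frame(probe_id = rownames(v), v, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write probe panel TSVs
#'
#' Columns: probe_id, transcript_id, strand, start, length, sequence,
#' is_control.
#'
#' @param path TSV path.
#' @return \code{readProbePanel}: a \linkS4class{ProbePanel}.
#' @export
readProbePanel <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    df$is_control <- as.logical(df$is_control)
    df$transcript_id[df$is_control] <- NA_character_
    ProbePanel(df)
}

#' @rdname readProbePanel
#' @param panel A \linkS4class{ProbePanel}.
#' @export
writeProbePanel <- function(panel, path) {
    write.table(probeTable(panel), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set id, description, then member gene ids (tab-separated,
#' ragged lines allowed). Lines with fewer than three fields are errors.
#'
#' @param path GMT file.
#' @return Named list of gene id vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("GMT line ", i, " has fewer than 3 fields")
        setNames(list(unique(f[-(1:2)])), f[1L])
    })
    do.call(c, sets)
}

#' Write gene sets to GMT
#'
#' @param geneSets Named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to "na").
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(geneSets, path, descriptions = NULL) {
    lines <- vapply(names(geneSets), function(nm) {
        d <- if (!is.null(descriptions) && nm %in% names(descriptions))
            descriptions[[nm]] else "na"
        paste(c(nm, d, geneSets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a two-column gene-to-category annotation TSV
#'
#' Header row \code{gene<TAB>category}; returns the category -> members
#' list used by the enrichment stage.
#'
#' @param path TSV path.
#' @return Named list, category id -> character vector of gene ids.
#' @export
readAnnotation <- function(path) {
    df <- read.delim(path, check.names = FALSE,
        colClasses = "character")
    if (!all(c("gene", "category") %in% names(df)))
        stop("annotation TSV needs columns 'gene' and 'category'")
    lapply(split(df$gene, df$category), unique)
}

#' @rdname readAnnotation
#' @param categoryMap Named list, gene -> categories (as produced by the
#'   generator), written out as the two-column table.
#' @export
writeAnnotation <- function(categoryMap, path) {
    df <- data.frame(
        gene = rep(names(categoryMap), lengths(categoryMap)),
        category = unlist(categoryMap, use.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
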