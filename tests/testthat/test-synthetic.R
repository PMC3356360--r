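test_that("generator is deterministic and honors degenerate sizes", {
    cfg <- generatorConfig(nTranscripts = 40, seed = 9)
    t1 <- simulateTranscriptome(cfg)
    t2 <- simulateTranscriptome(cfg)
    expect_identical(as.character(t1$sequences), as.character(t2$sequences))
    expect_identical(t1$info, t2$info)
    expect_identical(t1$geneSets, t2$geneSets)

    f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
    writeFasta(t1$sequences, f1); writeFasta(t2$sequences, f2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

    e <- simulateTranscriptome(generatorConfig(nTranscripts = 0, seed = 1))
    expect_equal(nrow(e$info), 0)
    expect_length(e$categoryMap, 0)
    expect_length(e$geneSets, 0)
})

test_that("length law has its histogram mode between 500 and 2000 bp", {
    tr <- simulateTranscriptome(generatorConfig(nTranscripts = 2000,
        seed = 4))
    h <- hist(tr$info$length, breaks = c(0, 500, 1000, 2000, 4000, Inf),
        plot = FALSE)
    modal <- which.max(h$counts)
    expect_true(h$breaks[modal] >= 500 && h$breaks[modal + 1] <= 2000)
    # heavy right tail: a visible fraction of transcripts beyond 4 kb
    expect_gt(mean(tr$info$length > 4000), 0.03)
    expect_equal(median(tr$info$length), 1000, tolerance = 0.1)
})

test_that("config validation rejects out-of-range parameters", {
    expect_error(generatorConfig(substitutionRate = 1.2), "rates")
    expect_error(generatorConfig(virusFraction = 0.2), "virusFraction")
    expect_error(generatorConfig(readLength = 10), "readLength")
    expect_error(generatorConfig(depth = 0), "depth")
})

test_that("noise-free assembler outputs equal the truth up to id renaming", {
    cfg <- generatorConfig(nTranscripts = 30, seed = 5,
        uniqueFraction = c(A = 0, B = 0),
        fragmentationRate = c(A = 0, B = 0),
        substitutionRate = 0, chimeraRate = 0)
    tr <- simulateTranscriptome(cfg)
    asm <- simulateAssemblerOutputs(tr)
    for (set in list(asm$A, asm$B)) {
        expect_equal(length(set), 30)
        map <- asm$truthMap[asm$truthMap$assembler == sourceLabel(set), ]
        expect_identical(
            unname(as.character(contigSequences(set))[map$contig_id]),
            unname(as.character(tr$sequences)[map$source_id]))
    }
})

test_that("per-assembler unique fractions match binomial accounting over 20 seeds", {
    nPer <- 150L; nSeeds <- 20L
    onlyB <- 0L; total <- 0L
    for (seed in seq_len(nSeeds)) {
        cfg <- generatorConfig(nTranscripts = nPer, seed = seed,
            uniqueFraction = c(A = 0, B = 0.1),
            fragmentationRate = c(A = 0, B = 0), substitutionRate = 0,
            chimeraRate = 0)
        tr <- simulateTranscriptome(cfg)
        asm <- simulateAssemblerOutputs(tr)
        onlyB <- onlyB + sum(asm$membership == "B")
        total <- total + length(asm$membership)
    }
    p <- 0.1
    sd3 <- 3 * sqrt(total * p * (1 - p))
    expect_lt(abs(onlyB - total * p), sd3)
})

test_that("substitution rate maps onto matched-pair identity", {
    cfg <- generatorConfig(nTranscripts = 40, seed = 13,
        uniqueFraction = c(A = 0, B = 0),
        fragmentationRate = c(A = 0, B = 0),
        substitutionRate = 0.01, chimeraRate = 0)
    tr <- simulateTranscriptome(cfg)
    asm <- simulateAssemblerOutputs(tr)
    truthSet <- ContigSet(tr$sequences, "truth")
    m <- findBestMatches(asm$A, truthSet)
    expect_true(all(m$matched))
    # per-base accounting: one mutated copy vs its source, ~99% identity
    expect_equal(mean(m$identity), 99, tolerance = 0.5 / 99)
})

test_that("reads are exact substrings when error-free, with opposite-strand mates", {
    cfg <- generatorConfig(nTranscripts = 12, seed = 6, depth = 6,
        paired = FALSE)
    tr <- simulateTranscriptome(cfg)
    rd <- simulateReads(tr)
    seqs <- setNames(as.character(tr$sequences), tr$info$id)
    hits <- mapply(function(read, src) grepl(read, seqs[[src]],
        fixed = TRUE), as.character(rd$reads), rd$truth$source_id)
    expect_true(all(hits))

    cfgP <- generatorConfig(nTranscripts = 8, seed = 6, depth = 4,
        paired = TRUE, insertSize = 214)
    trP <- simulateTranscriptome(cfgP)
    rdP <- suppressWarnings(simulateReads(trP))  # short transcripts skip
    tt <- rdP$truth
    m1 <- tt[tt$mate == 1L, ]; m2 <- tt[tt$mate == 2L, ]
    expect_true(all(m1$strand == "+") && all(m2$strand == "-"))
    # insert spans mate1 start to mate2 end at the configured size
    expect_true(all(m2$end - m1$start + 1L == 214))
    # mate 2 is the reverse complement of its template span
    i <- 1L
    span <- substr(seqs2 <- as.character(trP$sequences)[[m2$source_id[i]]],
        m2$start[i], m2$end[i])
    expect_equal(as.character(rdP$reads[[m2$read_id[i]]]), revcomp(span))
})

test_that("read counts follow the depth-by-length weighting", {
    cfg <- generatorConfig(nTranscripts = 30, seed = 7, depth = 650,
        paired = FALSE)
    tr <- simulateTranscriptome(cfg)
    rd <- simulateReads(tr)
    counts <- table(factor(rd$truth$source_id, levels = tr$info$id))
    cs <- coverageSummary(setNames(as.integer(counts), names(counts)),
        readLength = 100,
        refSet = ContigSet(tr$sequences, "truth"))
    # mean reads/contig ~ 650 at 100 bp reads on ~1 kb transcripts
    expected <- 650 * 100 / mean(tr$info$length)
    expect_equal(cs$mean_fold_coverage, expected, tolerance = 0.05)
    expect_warning(
        simulateReads(simulateTranscriptome(
            generatorConfig(nTranscripts = 300, seed = 8, depth = 1,
                insertSize = 500))),
        "skipped")
})

test_that("probe signals honor the strand ratio and planted fold changes exactly at zero noise", {
    cfg <- generatorConfig(nTranscripts = 15, seed = 10, noiseSd = 0,
        antisenseRatio = 10, deFractionUp = 0, deFractionDown = 0)
    tr <- simulateTranscriptome(cfg)
    panel <- designProbes(tr, nControls = 20, seed = 3)
    sig <- simulateProbeSignals(tr, panel)
    v <- intensities(sig$signal)
    tg <- targetProbes(panel)
    for (tid in tr$info$id[tr$info$class == "host"][1:5]) {
        pp <- tg$probe_id[tg$transcript_id == tid & tg$strand == "+"]
        pm <- tg$probe_id[tg$transcript_id == tid & tg$strand == "-"]
        ts <- tr$info$true_strand[tr$info$id == tid]
        ratio <- mean(v[pp, 1]) / mean(v[pm, 1])
        expect_equal(unname(ratio), if (ts == "+") 10 else 1 / 10,
            tolerance = 1e-9)
    }
    # no planted DE, zero noise: infected and uninfected columns identical
    host <- tg$probe_id[tg$transcript_id %in%
        tr$info$id[tr$info$class == "host"]]
    expect_equal(v[host, "I1"], v[host, "U1"], tolerance = 1e-12)
    # virus genes jump from background to full signal on infection
    vir <- tg$probe_id[tg$transcript_id %in%
        tr$info$id[tr$info$class == "virus"]]
    expect_true(all(v[vir, "I1"] > v[vir, "U1"]))
    # truth table records the planted labels exhaustively
    expect_setequal(sig$truth$id, tr$info$id)
    expect_true(all(sig$truth$regulation[sig$truth$class == "virus"] ==
        "up"))
})

test_that("signal generation rejects a panel referencing unknown transcripts", {
    cfg <- generatorConfig(nTranscripts = 5, seed = 2)
    tr <- simulateTranscriptome(cfg)
    bad <- ProbePanel(probeRow("p1", "NOPE", "+", 0, rseq(60, 1)))
    expect_error(simulateProbeSignals(tr, bad), "absent")
})

test_that("every contig and read traces to a truth record", {
    cfg <- generatorConfig(nTranscripts = 25, seed = 12, depth = 3,
        paired = FALSE)
    tr <- simulateTranscriptome(cfg)
    asm <- simulateAssemblerOutputs(tr)
    expect_setequal(asm$truthMap$contig_id,
        c(names(asm$A), names(asm$B)))
    expect_true(all(asm$truthMap$source_id %in% tr$info$id))
    rd <- simulateReads(tr)
    expect_setequal(rd$truth$read_id, names(rd$reads))
    expect_true(all(rd$truth$source_id %in% tr$info$id))
})
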