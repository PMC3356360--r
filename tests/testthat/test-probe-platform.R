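test_that("probe design yields verified strand-paired substrings and is deterministic", {
    seqs <- Biostrings::DNAStringSet(c(t1 = rseq(600, 51), t2 = rseq(59)))
    expect_warning(panel <- designProbes(seqs, nControls = 5, seed = 2),
        "skipped")
    tg <- targetProbes(panel)
    expect_equal(nrow(tg), 6)
    expect_equal(sum(tg$strand == "+"), 3)
    expect_false("t2" %in% tg$transcript_id)
    s <- as.character(seqs[["t1"]])
    for (i in seq_len(nrow(tg))) {
        sub <- substr(s, tg$start[i] + 1, tg$start[i] + 60)
        expected <- if (tg$strand[i] == "+") sub else revcomp(sub)
        expect_equal(tg$sequence[i], expected)
    }
    expect_equal(length(controlProbes(panel)), 5)
    panel2 <- suppressWarnings(designProbes(seqs, nControls = 5, seed = 2))
    expect_identical(probeTable(panel), probeTable(panel2))
})

test_that("cross-hybridization screening removes exactly the shared-segment probes", {
    # identical twins: every probe is removed
    twin <- rseq(300, 61)
    dup <- Biostrings::DNAStringSet(c(a = twin, b = twin))
    panel <- designProbes(dup, nControls = 0, seed = 3)
    sc <- screenCrossHybridization(panel, dup)
    expect_equal(length(sc$panel), 0)
    expect_equal(nrow(sc$removed), 12)

    # unrelated transcripts: nothing is removed
    uniq <- Biostrings::DNAStringSet(c(a = rseq(300, 62), b = rseq(300)))
    pu <- designProbes(uniq, nControls = 0, seed = 3)
    su <- screenCrossHybridization(pu, uniq)
    expect_equal(nrow(su$removed), 0)
    expect_equal(length(su$panel), length(pu))

    # one duplicated 60 bp segment: only probes overlapping it by >= 45
    # columns at >= 90% identity can be hit
    set.seed(63)
    t1 <- rseq(400)
    shared <- substr(t1, 101, 160)
    t2 <- paste0(rseq(200), shared, rseq(140))
    seqs <- Biostrings::DNAStringSet(c(t1 = t1, t2 = t2))
    probes <- rbind(
        probeRow("t1_in", "t1", "+", 100, substr(t1, 101, 160)),
        probeRow("t1_edge", "t1", "+", 130, substr(t1, 131, 190)),
        probeRow("t1_out", "t1", "+", 300, substr(t1, 301, 360)),
        probeRow("t2_in", "t2", "+", 200, substr(t2, 201, 260)),
        probeRow("t2_out", "t2", "+", 10, substr(t2, 11, 70)))
    sc2 <- screenCrossHybridization(ProbePanel(probes), seqs)
    expect_setequal(sc2$removed$probe_id, c("t1_in", "t2_in"))
})

test_that("WABS flags follow the background threshold and sample coverage rules", {
    # 2 target probes on one transcript strand trio + controls
    v <- rbind(
        p1 = c(100, 100, 100, 100),
        p2 = c(100, 100, 100, 4),    # drops out in one sample
        lo = c(5, 5, 5, 5),
        ctrl1 = c(4, 4, 4, 4), ctrl2 = c(5, 5, 5, 5),
        ctrl3 = c(6, 6, 6, 6))
    colnames(v) <- c("I1", "I2", "U1", "U2")
    sm <- smallSignalMatrix(v,
        is_control = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
    panel <- ProbePanel(rbind(
        probeRow("p1", "tA", "+", 0, rseq(60, 70)),
        probeRow("p2", "tB", "+", 0, rseq(60)),
        probeRow("lo", "tC", "+", 0, rseq(60))))
    fl <- wabsFlags(sm, panel, kSigma = 3)
    tt <- fl$transcripts
    expect_true(tt$wabs_all_samples[tt$transcript_id == "tA"])
    # WABS in 3 of 4 samples is not enough
    expect_false(tt$wabs_all_samples[tt$transcript_id == "tB"])
    # below background mean: never flagged
    expect_false(tt$wabs_all_samples[tt$transcript_id == "tC"])
    expect_false(any(fl$probeWabs["lo", ]))
})

test_that("WABS is monotone in the background multiplier", {
    set.seed(71)
    v <- matrix(2^rnorm(200 * 4, 6, 2), 200, 4,
        dimnames = list(sprintf("p%03d", 1:200), c("I1", "I2", "U1", "U2")))
    ctl <- seq_len(50)
    v[ctl, ] <- 2^rnorm(50 * 4, 4, 0.5)
    sm <- smallSignalMatrix(v,
        is_control = seq_len(200) %in% ctl)
    panel <- ProbePanel(do.call(rbind, lapply(51:200, function(i)
        probeRow(sprintf("p%03d", i), sprintf("t%03d", i), "+", 0,
            rseq(60)))))
    prev <- NULL
    for (k in c(1, 3, 6)) {
        fl <- wabsFlags(sm, panel, kSigma = k)
        if (!is.null(prev))
            expect_true(all(fl$probeWabs <= prev))
        prev <- fl$probeWabs
    }
})

test_that("WABS without controls demands explicit background statistics", {
    v <- matrix(c(10, 10, 10, 10), 1, 4,
        dimnames = list("p1", c("I1", "I2", "U1", "U2")))
    sm <- smallSignalMatrix(v)
    panel <- ProbePanel(probeRow("p1", "t1", "+", 0, rseq(60, 72)))
    expect_error(wabsFlags(sm, panel), "background")
    bg <- data.frame(sample_id = colnames(v), mean = 2, sd = 1)
    fl <- wabsFlags(sm, panel, background = bg)
    expect_true(all(fl$probeWabs))
})

test_that("orientation picks the strand with the highest cumulative signal", {
    v <- rbind(p1 = 100, p2 = 200, p3 = 300, m1 = 50, m2 = 60, m3 = 70)
    v <- cbind(v, v * 0 + 1e-6)  # one informative sample + a tiny second
    v <- v[, c(1, 2, 1, 2)]
    colnames(v) <- c("I1", "I2", "U1", "U2")
    panel <- ProbePanel(rbind(
        probeRow("p1", "t", "+", 0, rseq(60, 81)),
        probeRow("p2", "t", "+", 100, rseq(60)),
        probeRow("p3", "t", "+", 200, rseq(60)),
        probeRow("m1", "t", "-", 0, rseq(60)),
        probeRow("m2", "t", "-", 100, rseq(60)),
        probeRow("m3", "t", "-", 200, rseq(60))))
    sm <- smallSignalMatrix(v)
    oc <- inferOrientation(sm, panel)
    expect_equal(oc$chosen_strand, "+")
    expect_equal(oc$best_probe_id, "p3")
    expect_gte(oc$cum_signal_plus, oc$cum_signal_minus)

    # exact cumulative tie: strand with the larger single-probe maximum
    v2 <- rbind(p1 = 150, p2 = 150, p3 = 300, m1 = 250, m2 = 250,
        m3 = 100)
    v2 <- v2[, c(1, 1, 1, 1), drop = FALSE] / 4
    colnames(v2) <- c("I1", "I2", "U1", "U2")
    oc2 <- inferOrientation(smallSignalMatrix(v2), panel)
    expect_equal(oc2$cum_signal_plus, oc2$cum_signal_minus)
    expect_equal(oc2$chosen_strand, "+")

    # a strand without surviving probes leaves the call undetermined
    panelHalf <- ProbePanel(probeTable(panel)[1:3, ])
    oc3 <- inferOrientation(sm, panelHalf)
    expect_equal(oc3$chosen_strand, "undetermined")
})

test_that("orientation is invariant to per-sample positive rescaling", {
    cfg <- generatorConfig(nTranscripts = 40, seed = 26)
    tr <- simulateTranscriptome(cfg)
    panel <- designProbes(tr, nControls = 10, seed = 4)
    sig <- simulateProbeSignals(tr, panel)
    oc1 <- inferOrientation(sig$signal, panel)
    v <- intensities(sig$signal)
    scaled <- sweep(v, 2, c(3.7, 0.2, 11, 1.4), `*`)
    sm2 <- SignalMatrix(scaled, sampleConditions(sig$signal),
        c(1, 2, 1, 2), isControlProbe(sig$signal))
    oc2 <- inferOrientation(sm2, panel)
    # the strand decision is scale-free; the best-probe pick may move
    # within the chosen strand as samples are reweighted
    expect_equal(oc1$chosen_strand, oc2$chosen_strand)
})

test_that("orientation recovery is near-perfect at the platform's signal asymmetry", {
    cfg <- generatorConfig(nTranscripts = 400, seed = 27,
        antisenseRatio = 10, noiseSd = 0.25)
    tr <- simulateTranscriptome(cfg)
    panel <- designProbes(tr, nControls = 50, seed = 5)
    sig <- simulateProbeSignals(tr, panel)
    oc <- inferOrientation(sig$signal, panel)
    truth <- setNames(tr$info$true_strand, tr$info$id)
    det <- oc$chosen_strand != "undetermined"
    acc <- mean(oc$chosen_strand[det] == truth[oc$transcript_id[det]])
    expect_gte(acc, 0.99)

    # noise-free: recovery is exact and the best probe is the planted max
    cfg0 <- generatorConfig(nTranscripts = 50, seed = 28, noiseSd = 0)
    tr0 <- simulateTranscriptome(cfg0)
    p0 <- designProbes(tr0, nControls = 10, seed = 6)
    s0 <- simulateProbeSignals(tr0, p0)
    oc0 <- inferOrientation(s0$signal, p0)
    truth0 <- setNames(tr0$info$true_strand, tr0$info$id)
    expect_true(all(oc0$chosen_strand == truth0[oc0$transcript_id]))
    v0 <- rowSums(intensities(s0$signal))
    tg0 <- targetProbes(p0)
    for (i in seq_len(10)) {
        tid <- oc0$transcript_id[i]
        strandProbes <- tg0$probe_id[tg0$transcript_id == tid &
            tg0$strand == oc0$chosen_strand[i]]
        expect_equal(oc0$best_probe_id[i],
            strandProbes[which.max(v0[strandProbes])])
    }
})

test_that("platform report reproduces printed-percentage arithmetic", {
    expect_equal(percentOf(27431, 27873), 98.4)
    expect_equal(percentOf(22773, 27873), 81.7)
    expect_equal(percentOf(0, 100), 0.0)
    expect_true(is.na(percentOf(0, 0)))
})
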