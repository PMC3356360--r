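#' Configuration for the synthetic-data generator
#'
#' Collects every tunable of the simulated study: a transcriptome with a
#' long-tailed log-normal length law, two overlapping noisy assembler
#' outputs, 100 bp (paired) reads at high depth, and a 2-infected vs
#' 2-uninfected one-color probe-intensity experiment with three probes per
#' strand per transcript, strand-asymmetric signal, log-normal noise,
#' negative-control background probes, a small virus panel that is strongly
#' up-regulated on infection, and planted differentially expressed host genes
#' concentrated in designated categories and gene sets.
#'
#' @param nTranscripts Number of transcripts to simulate.
#' @param lengthMeanlog,lengthSdlog Log-normal length law (bp); defaults give
#'   median 1,000 bp with >5\% of transcripts longer than 4 kb.
#' @param minLength Floor on simulated transcript length (the transcript set
#'   emulated is already length-filtered at 200 bp).
#' @param virusFraction Fraction of transcripts in the virus panel, in
#'   (0, 0.05].
#' @param fragmentationRate Per-assembler probability (named A/B) that a
#'   transcript is emitted split in two.
#' @param substitutionRate Per-base substitution rate of assembler copies.
#' @param uniqueFraction Per-assembler probability (named A/B) that a
#'   transcript appears only in that assembler's output.
#' @param chimeraRate Probability an assembler contig is a fusion of two
#'   transcripts.
#' @param readLength Read length (bp), >= 20.
#' @param depth Mean reads per transcript (length-weighted Poisson counts).
#' @param paired Generate mate pairs (opposite orientations)?
#' @param insertSize Mean fragment size for paired reads (bp).
#' @param readSubstitutionRate Per-base sequencing error rate.
#' @param deFractionUp,deFractionDown Fractions of host genes planted up/down.
#' @param logfcMean,logfcSd Planted |log2 fold change| law (normal, truncated
#'   at 0.5).
#' @param noiseSd Probe-level log2-scale noise SD.
#' @param antisenseRatio Mean linear-scale signal ratio of true-strand to
#'   wrong-strand probes.
#' @param signalMeanlog2,signalSdlog2 Log2-scale law of per-gene expression
#'   levels.
#' @param backgroundOffset Log2 units separating mean background from mean
#'   true signal.
#' @param backgroundSdlog2 Log2-scale SD of the background (negative-control)
#'   law.
#' @param nControls Number of negative-control probes on the array.
#' @param nCategories Number of GO-style categories; the first two are
#'   designated up-enriched, the next two down-enriched.
#' @param categoryConcentration Fraction of planted DE genes drawn from the
#'   designated categories.
#' @param geneSetSize Size of each of the five immune-pathway-style gene
#'   sets (apoptosis, toll, jak_stat, imd, jnk).
#' @param geneSetConcentration Fraction of the apoptosis set drawn from
#'   planted up genes (toll/jak_stat likewise from planted down genes).
#' @param seed Integer master seed; each stage derives its own substream, so
#'   a fixed seed yields byte-identical artifacts.
#' @return A validated \code{GeneratorConfig} object.
#' @examples
#' cfg <- generatorConfig(nTranscripts = 50, seed = 7)
#' @export
generatorConfig <- function(nTranscripts = 500L,
        lengthMeanlog = log(1000), lengthSdlog = 0.9, minLength = 201L,
        virusFraction = 0.005,
        fragmentationRate = c(A = 0.05, B = 0.05),
        substitutionRate = 0.005,
        uniqueFraction = c(A = 0.10, B = 0.04),
        chimeraRate = 0.005,
        readLength = 100L, depth = 650, paired = TRUE, insertSize = 214L,
        readSubstitutionRate = 0,
        deFractionUp = 0.05, deFractionDown = 0.05,
        logfcMean = 2, logfcSd = 0,
        noiseSd = 0.25, antisenseRatio = 10,
        signalMeanlog2 = 10, signalSdlog2 = 2,
        backgroundOffset = 6, backgroundSdlog2 = 0.5,
        nControls = 100L,
        nCategories = 40L, categoryConcentration = 0.5,
        geneSetSize = 30L, geneSetConcentration = 0.6,
        seed = 1L) {
    cfg <- list(nTranscripts = as.integer(nTranscripts),
        lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
        minLength = as.integer(minLength), virusFraction = virusFraction,
        fragmentationRate = fragmentationRate,
        substitutionRate = substitutionRate,
        uniqueFraction = uniqueFraction, chimeraRate = chimeraRate,
        readLength = as.integer(readLength), depth = depth,
        paired = paired, insertSize = as.integer(insertSize),
        readSubstitutionRate = readSubstitutionRate,
        deFractionUp = deFractionUp, deFractionDown = deFractionDown,
        logfcMean = logfcMean, logfcSd = logfcSd,
        noiseSd = noiseSd, antisenseRatio = antisenseRatio,
        signalMeanlog2 = signalMeanlog2, signalSdlog2 = signalSdlog2,
        backgroundOffset = backgroundOffset,
        backgroundSdlog2 = backgroundSdlog2,
        nControls = as.integer(nControls),
        nCategories = as.integer(nCategories),
        categoryConcentration = categoryConcentration,
        geneSetSize = as.integer(geneSetSize),
        geneSetConcentration = geneSetConcentration,
        seed = as.integer(seed))
    class(cfg) <- "GeneratorConfig"
    rates <- c(cfg$fragmentationRate, cfg$substitutionRate,
        cfg$uniqueFraction, cfg$chimeraRate, cfg$deFractionUp,
        cfg$deFractionDown, cfg$readSubstitutionRate,
        cfg$categoryConcentration, cfg$geneSetConcentration)
    if (any(rates < 0 | rates > 1))
        stop("all rates and fractions must lie in [0, 1]")
    if (cfg$nTranscripts < 0L) stop("nTranscripts must be >= 0")
    if (cfg$virusFraction <= 0 || cfg$virusFraction > 0.05)
        stop("virusFraction must lie in (0, 0.05]")
    if (cfg$readLength < 20L) stop("readLength must be >= 20")
    if (cfg$depth <= 0) stop("depth must be > 0")
    if (cfg$noiseSd < 0 || cfg$backgroundSdlog2 < 0)
        stop("noise SDs must be >= 0")
    if (cfg$antisenseRatio < 1) stop("antisenseRatio must be >= 1")
    if (sum(cfg$uniqueFraction) > 1)
        stop("uniqueFraction values must sum to <= 1")
    if (is.na(cfg$seed)) stop("seed must be a finite integer")
    cfg
}

# Stage substreams derived from the master seed: reproducible per stage
# regardless of which stages ran before.
stageSeed <- function(config, stage) {
    offsets <- c(transcriptome = 11L, assemblies = 23L, reads = 37L,
        probes = 53L, signals = 71L)
    (abs(config$seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

randomSequence <- function(lengths) {
    vapply(lengths, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1))
}

mutateSequence <- function(seq, rate) {
    if (rate <= 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < rate)
    if (length(hit)) {
        alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
        chars[hit] <- vapply(chars[hit], function(b) {
            i <- sample.int(3L, 1L)
            substr(alt[[b]], i, i)
        }, character(1), USE.NAMES = FALSE)
        seq <- paste(chars, collapse = "")
    }
    seq
}

#' Simulate a truth transcriptome with planted expression structure
#'
#' Draws transcript lengths from the configured log-normal law, assigns a
#' small virus panel, plants up/down-regulated host genes with the
#' configured effect sizes (concentrated in designated categories), and
#' builds GO-style category annotations plus five immune-pathway-style gene
#' sets (apoptosis enriched among planted up genes, toll and jak_stat among
#' planted down genes, imd and jnk neutral).
#'
#' @param config A \code{\link{generatorConfig}}.
#' @return A list of class \code{TruthTranscriptome}: \code{sequences}
#'   (named DNAStringSet), \code{info} (data.frame: id, length, true_strand,
#'   class, true_logfc, regulation), \code{categoryMap} (gene id -> character
#'   vector of categories), \code{geneSets} (named list of gene id vectors),
#'   \code{config}.
#' @export
simulateTranscriptome <- function(config) {
    stopifnot(inherits(config, "GeneratorConfig"))
    n <- config$nTranscripts
    if (n == 0L) {
        return(structure(list(
            sequences = Biostrings::DNAStringSet(),
            info = data.frame(id = character(), length = integer(),
                true_strand = character(), class = character(),
                true_logfc = numeric(), regulation = character()),
            categoryMap = list(), geneSets = list(), config = config),
            class = "TruthTranscriptome"))
    }
    withSeed(stageSeed(config, "transcriptome"), {
        lens <- pmax(config$minLength,
            as.integer(round(rlnorm(n, config$lengthMeanlog,
                config$lengthSdlog))))
        nVirus <- max(1L, round(config$virusFraction * n))
        if (nVirus / n > 0.05) nVirus <- max(1L, floor(0.05 * n))
        cls <- rep("host", n)
        cls[sample.int(n, nVirus)] <- "virus"
        ids <- character(n)
        ids[cls == "host"] <- sprintf("HOST%05d", seq_len(n - nVirus))
        ids[cls == "virus"] <- sprintf("VIRUS%03d", seq_len(nVirus))
        strand <- sample(c("+", "-"), n, replace = TRUE)
        seqs <- Biostrings::DNAStringSet(setNames(randomSequence(lens), ids))

        host <- ids[cls == "host"]
        nHost <- length(host)
        nCat <- config$nCategories
        catIds <- sprintf("cat%02d", seq_len(nCat))
        # each host gene gets one primary category, ~30% get a second
        primary <- sample(catIds, nHost, replace = TRUE)
        categoryMap <- as.list(primary)
        extra <- runif(nHost) < 0.3
        categoryMap[extra] <- Map(function(a, b) unique(c(a, b)),
            categoryMap[extra],
            sample(catIds, sum(extra), replace = TRUE))
        names(categoryMap) <- host

        upCats <- catIds[seq_len(min(2L, nCat))]
        downCats <- catIds[seq_len(min(4L, nCat))][-seq_len(min(2L, nCat))]
        pickConcentrated <- function(k, cats) {
            inCat <- host[vapply(categoryMap, function(cc)
                any(cc %in% cats), logical(1))]
            nIn <- min(length(inCat), round(config$categoryConcentration * k))
            c(sample(inCat, nIn),
                sample(setdiff(host, inCat), k - nIn))
        }
        nUp <- round(config$deFractionUp * nHost)
        nDown <- round(config$deFractionDown * nHost)
        upGenes <- if (nUp > 0) pickConcentrated(nUp, upCats) else character()
        downGenes <- if (nDown > 0)
            pickConcentrated(nDown, downCats) else character()
        downGenes <- setdiff(downGenes, upGenes)

        lfc <- setNames(numeric(n), ids)
        mag <- function(k) pmax(0.5,
            config$logfcMean + config$logfcSd * rnorm(k))
        lfc[upGenes] <- mag(length(upGenes))
        lfc[downGenes] <- -mag(length(downGenes))
        reg <- setNames(rep("unchanged", n), ids)
        reg[upGenes] <- "up"
        reg[downGenes] <- "down"
        reg[cls == "virus"] <- "up"   # virus panel switches on at infection

        mkSet <- function(size, pool, conc) {
            size <- min(size, nHost)
            nIn <- min(length(pool), round(conc * size))
            unique(c(sample(pool, nIn),
                sample(setdiff(host, pool), size - nIn)))
        }
        gsSize <- config$geneSetSize
        geneSets <- list(
            apoptosis = mkSet(gsSize, upGenes, config$geneSetConcentration),
            toll = mkSet(gsSize, downGenes, config$geneSetConcentration),
            jak_stat = mkSet(gsSize, downGenes, config$geneSetConcentration),
            imd = mkSet(gsSize, character(), 0),
            jnk = mkSet(gsSize, character(), 0))

        structure(list(sequences = seqs,
            info = data.frame(id = ids, length = lens, true_strand = strand,
                class = cls, true_logfc = unname(lfc),
                regulation = unname(reg)),
            categoryMap = categoryMap, geneSets = geneSets,
            config = config), class = "TruthTranscriptome")
    })
}

#' Simulate two assembler outputs from a truth transcriptome
#'
#' Each transcript is assigned to both outputs, or exclusively to one with
#' the configured per-assembler unique fractions. Assembler copies are
#' per-base mutated at \code{substitutionRate}, occasionally emitted as two
#' fragments (\code{fragmentationRate}) and occasionally fused with another
#' transcript (\code{chimeraRate}) — the realistic failure modes the
#' assembly-comparison stage has to absorb.
#'
#' @param truth A \code{TruthTranscriptome}.
#' @param config A \code{\link{generatorConfig}} (defaults to the truth's).
#' @return list with ContigSets \code{A} and \code{B} and \code{truthMap}, a
#'   data.frame (contig_id, source_id, assembler, chimera_of) tracing every
#'   contig to its source transcript.
#' @export
simulateAssemblerOutputs <- function(truth, config = truth$config) {
    stopifnot(inherits(truth, "TruthTranscriptome"))
    n <- nrow(truth$info)
    if (n == 0L) stop("truth transcriptome is empty")
    withSeed(stageSeed(config, "assemblies"), {
        ufA <- config$uniqueFraction[["A"]]
        ufB <- config$uniqueFraction[["B"]]
        u <- runif(n)
        membership <- ifelse(u < ufA, "A", ifelse(u < ufA + ufB, "B", "AB"))
        seqs <- as.character(truth$sequences)
        ids <- truth$info$id
        buildOne <- function(which) {
            keep <- which(membership %in% c(which, "AB"))
            frate <- config$fragmentationRate[[which]]
            out_id <- character(0); out_seq <- character(0)
            src <- character(0); chim <- character(0)
            k <- 0L
            for (i in keep) {
                s <- mutateSequence(seqs[i], config$substitutionRate)
                chimPartner <- NA_character_
                if (runif(1) < config$chimeraRate && n > 1L) {
                    j <- sample(setdiff(seq_len(n), i), 1L)
                    s <- paste0(s, mutateSequence(seqs[j],
                        config$substitutionRate))
                    chimPartner <- ids[j]
                }
                pieces <- s
                if (is.na(chimPartner) && nchar(s) >= 500L &&
                        runif(1) < frate) {
                    cut <- sample(200:(nchar(s) - 200), 1L)
                    pieces <- c(substr(s, 1L, cut),
                        substr(s, cut + 1L, nchar(s)))
                }
                for (p in pieces) {
                    k <- k + 1L
                    out_id <- c(out_id, sprintf("%s_%06d", which, k))
                    out_seq <- c(out_seq, p)
                    src <- c(src, ids[i])
                    chim <- c(chim, chimPartner)
                }
            }
            list(set = ContigSet(setNames(out_seq, out_id), which),
                map = data.frame(contig_id = out_id, source_id = src,
                    assembler = which, chimera_of = chim))
        }
        a <- buildOne("A")
        b <- buildOne("B")
        list(A = a$set, B = b$set, truthMap = rbind(a$map, b$map),
            membership = setNames(membership, ids))
    })
}

#' Simulate sequencing reads from a truth transcriptome
#'
#' Read counts per transcript are Poisson with mean
#' \code{depth * length / mean(length)}; start positions are uniform.
#' In paired mode each fragment yields two opposite-orientation mates at the
#' configured insert size. Transcripts shorter than the read length are
#' skipped with a warning.
#'
#' @param truth A \code{TruthTranscriptome}.
#' @param config A \code{\link{generatorConfig}} (defaults to the truth's).
#' @return list with \code{reads} (named DNAStringSet) and \code{truth}
#'   (data.frame: read_id, source_id, start, end, strand, mate).
#' @export
simulateReads <- function(truth, config = truth$config) {
    stopifnot(inherits(truth, "TruthTranscriptome"))
    if (nrow(truth$info) == 0L)
        return(list(reads = Biostrings::DNAStringSet(),
            truth = data.frame(read_id = character(),
                source_id = character(), start = integer(),
                end = integer(), strand = character(), mate = integer())))
    withSeed(stageSeed(config, "reads"), {
        rl <- config$readLength
        lens <- truth$info$length
        usable <- lens >= if (config$paired)
            max(rl, config$insertSize) else rl
        if (any(!usable))
            warning(sum(!usable), " transcript(s) shorter than the ",
                "read/fragment length were skipped")
        seqs <- as.character(truth$sequences)
        ids <- truth$info$id
        meanLen <- mean(lens[usable])
        outSeq <- character(0); outId <- character(0)
        tr <- vector("list", sum(usable))
        ti <- 0L
        for (i in which(usable)) {
            nr <- rpois(1L, config$depth * lens[i] / meanLen)
            if (nr == 0L) next
            frag <- if (config$paired) config$insertSize else rl
            starts <- sample.int(lens[i] - frag + 1L, nr, replace = TRUE)
            s1 <- substring(seqs[i], starts, starts + rl - 1L)
            if (config$readSubstitutionRate > 0)
                s1 <- vapply(s1, mutateSequence,
                    rate = config$readSubstitutionRate, character(1),
                    USE.NAMES = FALSE)
            id1 <- sprintf("%s_r%d/1", ids[i], seq_len(nr))
            ti <- ti + 1L
            if (config$paired) {
                e2 <- starts + frag - 1L
                m2fwd <- substring(seqs[i], e2 - rl + 1L, e2)
                s2 <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(m2fwd)))
                if (config$readSubstitutionRate > 0)
                    s2 <- vapply(s2, mutateSequence,
                        rate = config$readSubstitutionRate, character(1),
                        USE.NAMES = FALSE)
                id2 <- sprintf("%s_r%d/2", ids[i], seq_len(nr))
                outSeq <- c(outSeq, s1, s2)
                outId <- c(outId, id1, id2)
                tr[[ti]] <- data.frame(
                    read_id = c(id1, id2), source_id = ids[i],
                    start = c(starts, e2 - rl + 1L),
                    end = c(starts + rl - 1L, e2),
                    strand = rep(c("+", "-"), each = nr),
                    mate = rep(c(1L, 2L), each = nr))
            } else {
                outSeq <- c(outSeq, s1)
                outId <- c(outId, id1)
                tr[[ti]] <- data.frame(read_id = id1, source_id = ids[i],
                    start = starts, end = starts + rl - 1L,
                    strand = "+", mate = 1L)
            }
        }
        list(reads = Biostrings::DNAStringSet(setNames(outSeq, outId)),
            truth = do.call(rbind, tr[seq_len(ti)]))
    })
}

#' Simulate probe-level hybridization intensities with planted truth
#'
#' Every gene draws a log2 expression level from the signal law. Probes on
#' the gene's true strand report that level; wrong-strand probes report it
#' reduced by \code{log2(antisenseRatio)}. Planted differentially expressed
#' host genes shift the infected columns by their true log2 fold change;
#' virus genes sit at background in uninfected samples and at full signal in
#' infected ones. Probe-level log-normal noise (\code{noiseSd}, log2 scale)
#' and negative-control probes drawn from the background law complete the
#' matrix.
#'
#' @param truth A \code{TruthTranscriptome}.
#' @param panel A \linkS4class{ProbePanel} whose target probes reference
#'   transcripts present in \code{truth}.
#' @param config A \code{\link{generatorConfig}} (defaults to the truth's).
#' @return list with \code{signal} (a \linkS4class{SignalMatrix}, samples
#'   I1, I2, U1, U2) and \code{truth} (data.frame: gene id, class,
#'   true_strand, true_logfc, regulation).
#' @export
simulateProbeSignals <- function(truth, panel, config = truth$config) {
    stopifnot(inherits(truth, "TruthTranscriptome"), is(panel, "ProbePanel"))
    probes <- probeTable(panel)
    targets <- probes[!probes$is_control, , drop = FALSE]
    if (nrow(targets) && !all(targets$transcript_id %in% truth$info$id))
        stop("probe panel references transcripts absent from the truth set")
    withSeed(stageSeed(config, "signals"), {
        samples <- c("I1", "I2", "U1", "U2")
        condition <- c("infected", "infected", "uninfected", "uninfected")
        info <- truth$info
        rownames(info) <- info$id
        bgMean <- config$signalMeanlog2 - config$backgroundOffset
        mu <- setNames(rnorm(nrow(info), config$signalMeanlog2,
            config$signalSdlog2), info$id)
        # per-gene log2 means by condition
        uninf <- ifelse(info$class == "virus", bgMean, mu[info$id])
        infc <- ifelse(info$class == "virus", mu[info$id],
            mu[info$id] + info$true_logfc)
        names(uninf) <- names(infc) <- info$id
        trueLfc <- setNames(infc - uninf, info$id)

        m <- matrix(NA_real_, nrow(probes), 4L,
            dimnames = list(probes$probe_id, samples))
        isCtl <- probes$is_control
        if (any(!isCtl)) {
            g <- probes$transcript_id[!isCtl]
            senseMatch <- probes$strand[!isCtl] == info[g, "true_strand"]
            penalty <- ifelse(senseMatch, 0, log2(config$antisenseRatio))
            base <- cbind(infc[g], infc[g], uninf[g], uninf[g]) - penalty
            m[!isCtl, ] <- base +
                config$noiseSd * matrix(rnorm(sum(!isCtl) * 4L),
                    ncol = 4L)
        }
        if (any(isCtl))
            m[isCtl, ] <- bgMean +
                config$backgroundSdlog2 * matrix(rnorm(sum(isCtl) * 4L),
                    ncol = 4L)
        sm <- SignalMatrix(2^m, condition, c(1L, 2L, 1L, 2L),
            is_control = isCtl)
        list(signal = sm,
            truth = data.frame(id = info$id, class = info$class,
                true_strand = info$true_strand,
                true_logfc = unname(trueLfc[info$id]),
                regulation = info$regulation))
    })
}
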