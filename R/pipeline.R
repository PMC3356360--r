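#' Invert a gene-to-category map
#'
#' @param categoryMap Named list, gene id -> character vector of categories.
#' @return Named list, category id -> character vector of member genes.
#' @export
invertAnnotation <- function(categoryMap) {
    df <- data.frame(
        gene = rep(names(categoryMap), lengths(categoryMap)),
        category = unlist(categoryMap, use.names = FALSE))
    lapply(split(df$gene, df$category), unique)
}

#' Pipeline configuration
#'
#' Collects every stage threshold with its default: the 200 bp length
#' filter and the 200 bp / 95\% redundancy rule of the merge, the 95\%
#' length / 90\% identity read-mapping criteria, the background + 3 SD WABS
#' rule, the 0.05 adjusted-p and 2-fold DE thresholds, and the GSEA weight
#' and permutation count. Unknown arguments and out-of-range thresholds are
#' rejected before any stage runs.
#'
#' @param minLength Merge length filter (bp).
#' @param minIdentity,minAligned Redundancy thresholds (percent, bp).
#' @param mapLenFrac,mapId Read-mapping acceptance criteria (fractions).
#' @param kSigma WABS background SD multiplier.
#' @param alpha Adjusted-p threshold for DE calls.
#' @param fcFold Fold-change threshold (linear scale).
#' @param gseaWeight,nperm GSEA hit weight and permutation count.
#' @param seed Master seed (also passed to the generator).
#' @param generator A \code{\link{generatorConfig}} for the simulate stage.
#' @param stages Character subset of
#'   c("simulate","merge","platform","de","enrich"), executed in that
#'   order; any prefix is allowed.
#' @param primaryFasta,secondaryFasta Optional FASTA paths used by the
#'   merge stage instead of simulated assemblies.
#' @param outdir Optional directory; when set, every stage writes its
#'   tables/FASTA there and the manifest records their checksums.
#' @return Validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(minLength = 200, minIdentity = 95,
        minAligned = 200, mapLenFrac = 0.95, mapId = 0.90, kSigma = 3,
        alpha = 0.05, fcFold = 2, gseaWeight = 1, nperm = 1000L,
        seed = 1L, generator = generatorConfig(seed = seed),
        stages = c("simulate", "merge", "platform", "de", "enrich"),
        primaryFasta = NULL, secondaryFasta = NULL, outdir = NULL) {
    known <- c("simulate", "merge", "platform", "de", "enrich")
    if (!all(stages %in% known))
        stop("unknown stage(s): ",
            paste(setdiff(stages, known), collapse = ", "))
    if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
    if (minLength < 0 || minAligned < 0) stop("lengths must be >= 0")
    if (minIdentity < 0 || minIdentity > 100)
        stop("minIdentity must lie in [0, 100]")
    if (mapLenFrac <= 0 || mapLenFrac > 1 || mapId <= 0 || mapId > 1)
        stop("mapping criteria must lie in (0, 1]")
    if (kSigma < 0) stop("kSigma must be >= 0")
    if (fcFold < 1) stop("fcFold must be >= 1")
    if (nperm < 1) stop("nperm must be >= 1")
    structure(list(minLength = minLength, minIdentity = minIdentity,
        minAligned = minAligned, mapLenFrac = mapLenFrac, mapId = mapId,
        kSigma = kSigma, alpha = alpha, fcFold = fcFold,
        gseaWeight = gseaWeight, nperm = as.integer(nperm),
        seed = as.integer(seed), generator = generator,
        stages = intersect(known, stages), primaryFasta = primaryFasta,
        secondaryFasta = secondaryFasta, outdir = outdir),
        class = "PipelineConfig")
}

writeStage <- function(outdir, name, writer) {
    if (is.null(outdir)) return(NULL)
    path <- file.path(outdir, name)
    writer(path)
    path
}

#' Run the pipeline end to end on synthetic data
#'
#' Executes the configured stage prefix in order
#' simulate -> merge -> platform -> de -> enrich and returns every stage's
#' result plus a run manifest (parameter values, seeds, stage output sizes
#' and, when \code{outdir} is set, md5 checksums of every written file)
#' sufficient to verify byte-identical reproduction.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return list with elements per executed stage (\code{truth},
#'   \code{assemblies}, \code{merge}, \code{platform}, \code{de},
#'   \code{enrich}) and \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    res <- list()
    manifest <- list(parameters = config[setdiff(names(config),
        c("generator", "outdir"))],
        generator = unclass(config$generator), files = list(),
        stage_sizes = list())
    outdir <- config$outdir
    if (!is.null(outdir) &&
            !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    runStage <- function(name, fun) {
        tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                call. = FALSE))
    }

    if ("simulate" %in% config$stages) {
        res$truth <- runStage("simulate", function()
            simulateTranscriptome(config$generator))
        res$assemblies <- runStage("simulate", function()
            simulateAssemblerOutputs(res$truth))
        manifest$stage_sizes$simulate <- c(
            transcripts = nrow(res$truth$info),
            contigs_A = length(res$assemblies$A),
            contigs_B = length(res$assemblies$B))
        writeStage(outdir, "truth_transcripts.fasta", function(p)
            writeFasta(res$truth$sequences, p))
        writeStage(outdir, "assembly_A.fasta", function(p)
            writeFasta(res$assemblies$A, p))
        writeStage(outdir, "assembly_B.fasta", function(p)
            writeFasta(res$assemblies$B, p))
        writeStage(outdir, "truth_table.tsv", function(p)
            write.table(res$truth$info, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
    }

    if ("merge" %in% config$stages) {
        res$merge <- runStage("merge", function() {
            if (!is.null(config$primaryFasta)) {
                primary <- readFasta(config$primaryFasta, "primary")
                secondary <- readFasta(config$secondaryFasta, "secondary")
            } else {
                if (is.null(res$assemblies))
                    stop("no assemblies: run the simulate stage or give ",
                        "primaryFasta/secondaryFasta")
                primary <- res$assemblies$B   # backbone assembly
                secondary <- res$assemblies$A
            }
            mergeAssemblies(primary, secondary,
                minLength = config$minLength,
                minAligned = config$minAligned,
                minIdentity = config$minIdentity)
        })
        manifest$stage_sizes$merge <-
            c(n_final = res$merge$report$n_final)
        writeStage(outdir, "merged.fasta", function(p)
            writeFasta(res$merge$merged, p))
        writeStage(outdir, "matches.tsv", function(p)
            write.table(res$merge$matches, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
    }

    if ("platform" %in% config$stages) {
        res$platform <- runStage("platform", function() {
            if (is.null(res$truth))
                stop("platform stage needs the simulate stage")
            # probes target the non-redundant set's source transcripts
            srcIds <- if (!is.null(res$merge)) {
                tm <- res$assemblies$truthMap
                mergedIds <- names(res$merge$merged)
                # unique secondary contigs may carry a source-label prefix
                bare <- sub(paste0("^", sourceLabel(res$assemblies$A),
                    "_(?=[A-Z])"), "", mergedIds, perl = TRUE)
                unique(tm$source_id[tm$contig_id %in%
                    unique(c(mergedIds, bare))])
            } else res$truth$info$id
            seqs <- res$truth$sequences[
                intersect(res$truth$info$id, srcIds)]
            panel <- designProbes(seqs, seed = config$seed,
                nControls = config$generator$nControls)
            screened <- screenCrossHybridization(panel,
                res$truth$sequences)
            sig <- simulateProbeSignals(res$truth, screened$panel)
            flags <- wabsFlags(sig$signal, screened$panel,
                kSigma = config$kSigma)
            calls <- inferOrientation(sig$signal, screened$panel)
            list(panel = screened$panel, removed = screened$removed,
                signal = sig$signal, signalTruth = sig$truth,
                flags = flags, calls = calls,
                report = platformReport(flags, calls, screened$panel))
        })
        manifest$stage_sizes$platform <- c(
            probes = length(res$platform$panel),
            on_array = res$platform$report$n_on_array)
        writeStage(outdir, "probe_panel.tsv", function(p)
            writeProbePanel(res$platform$panel, p))
        writeStage(outdir, "signal_matrix.tsv", function(p)
            writeSignalMatrix(res$platform$signal, p))
        writeStage(outdir, "orientation_calls.tsv", function(p)
            write.table(res$platform$calls, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
    }

    if ("de" %in% config$stages) {
        res$de <- runStage("de", function() {
            if (is.null(res$platform))
                stop("de stage needs the platform stage")
            gm <- geneSignalMatrix(res$platform$signal,
                res$platform$calls)
            lab <- setNames(res$truth$info$class, res$truth$info$id)
            panels <- splitPanels(gm, lab)
            condition <- unname(sampleConditions(res$platform$signal))
            host <- runDEPanel(panels$host, condition,
                alpha = config$alpha, fcFold = config$fcFold)
            virus <- if (nrow(panels$virus) >= 10L)
                runDEPanel(panels$virus, condition,
                    alpha = config$alpha, fcFold = config$fcFold)
            else if (nrow(panels$virus) > 0L) {
                # too few virus genes for an empirical-Bayes ensemble:
                # report fold changes descriptively
                lv <- log2(panels$virus + 1)
                f <- fitTwoGroup(lv, condition)
                list(table = f, summary = NULL, params = NULL,
                    normalized = lv)
            } else NULL
            list(host = host, virus = virus,
                replicate_r = replicateCorrelation(
                    log2(panels$host + 1),
                    pairs = list(c("I1", "I2"), c("U1", "U2"))))
        })
        manifest$stage_sizes$de <-
            c(host_genes = nrow(res$de$host$table))
        writeStage(outdir, "de_host.tsv", function(p)
            write.table(res$de$host$table, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
    }

    if ("enrich" %in% config$stages) {
        res$enrich <- runStage("enrich", function() {
            if (is.null(res$de)) stop("enrich stage needs the de stage")
            calls <- setNames(res$de$host$table$call,
                res$de$host$table$gene_id)
            annotation <- invertAnnotation(
                res$truth$categoryMap[names(calls)[names(calls) %in%
                    names(res$truth$categoryMap)]])
            stat <- setNames(res$de$host$table$t_mod,
                res$de$host$table$gene_id)
            list(scores = deltaProportionScores(calls, annotation),
                hyper_up = hyperEnrichment(calls, annotation, "up"),
                hyper_down = hyperEnrichment(calls, annotation, "down"),
                gsea = gseaEnrichment(stat, res$truth$geneSets,
                    weight = config$gseaWeight, nperm = config$nperm,
                    seed = config$seed))
        })
        writeStage(outdir, "category_scores.tsv", function(p)
            write.table(res$enrich$scores, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
        writeStage(outdir, "gsea.tsv", function(p)
            write.table(res$enrich$gsea, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
    }

    if (!is.null(outdir)) {
        files <- list.files(outdir, full.names = TRUE)
        manifest$files <- as.list(tools::md5sum(files))
        names(manifest$files) <- basename(files)
    }
    res$manifest <- manifest
    res
}
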