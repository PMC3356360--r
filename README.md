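# NovoArray

Building a species-specific expression platform when no genome exists:
from two de novo transcriptome assemblies to a validated oligonucleotide
microarray and host/virus differential-expression analysis.

## The problem

For non-model organisms — here the motivating system is a lepidopteran
insect cell line infected by a baculovirus — there is often no reference
genome, so expression platforms must be bootstrapped from RNA-seq. Two
short-read assemblers run on the same reads produce overlapping but
different contig sets; reconciling them yields a more complete,
non-redundant transcript catalogue. Because de novo assembly does not
record which strand is the mRNA sense strand, a validation microarray with
probes on *both* strands of every transcript can recover orientation from
hybridization signal while simultaneously filtering unexpressed or
misassembled sequences. The resulting one-best-probe-per-gene platform then
supports a small-replicate infection experiment (2 infected vs 2 uninfected
samples) analysed with empirical-Bayes moderated statistics and gene-set
enrichment.

NovoArray implements that whole workflow as reusable, tested R components,
plus a synthetic-data generator with planted ground truth so every stage
can be exercised end to end without external downloads.

## What is inside

- **Assembly reconciliation** (`findBestMatches`, `classifyUnique`,
  `mergeAssemblies`, `assemblyStats`, `mapReads`, `coverageSummary`): a
  deterministic BLASTN-style local aligner (exact 15-mer seeds, diagonal
  chaining, banded Smith–Waterman extension with match +1 / mismatch −2 /
  gap −3, implemented in C++) compares the two assemblies; a secondary
  contig is *redundant* iff its best hit has aligned length ≥ 200 bp and
  identity ≥ 95 %, and only unique contigs are added to the backbone
  assembly. QC includes N50/length histograms and read-mapping coverage
  (a read counts iff it aligns over ≥ 95 % of its length at ≥ 90 %
  identity; mean fold coverage = mean reads per contig × read length /
  mean contig length).
- **Probe platform** (`designProbes`, `screenCrossHybridization`,
  `wabsFlags`, `inferOrientation`, `platformReport`): three 60-mer probes
  per strand per transcript, cross-hybridization screening through the
  same aligner, well-above-background (WABS) calls at background mean +
  3 SD from negative-control probes, and strand inference by the highest
  cumulative probe signal, keeping the single best probe per gene.
- **Differential expression** (`splitPanels`, `quantileNormalize`,
  `fitTwoGroup`, `moderateFit`, `bhAdjust`, `classifyDE`, `runDEPanel`):
  virus genes are split from host genes before quantile normalization;
  per-gene variances are shrunk by empirical Bayes (prior df and prior
  variance estimated by digamma/trigamma moment matching of log s²), and
  the moderated t with Benjamini–Hochberg adjustment calls genes up/down
  at adjusted p < 0.05, with a 2-fold sub-classification and a log-odds
  (B) ranking statistic.
- **Enrichment** (`deltaProportionScores`, `hyperEnrichment`,
  `slimRollup`, `gseaEnrichment`): per-category score u/N − d/N,
  one-sided hypergeometric over-representation with BH, GO-slim roll-ups,
  and weighted running-sum GSEA (ES, permutation-normalized NES, nominal
  p and FDR q from random same-size gene sets; FDR decision rule 0.25).
- **Synthetic data** (`generatorConfig`, `simulateTranscriptome`,
  `simulateAssemblerOutputs`, `simulateReads`, `simulateProbeSignals`):
  log-normal transcript lengths (median ≈ 1 kb, heavy right tail), two
  noisy overlapping assembler outputs, 100 bp (paired) reads, and a
  4-sample probe-intensity matrix with a 10:1 sense/antisense signal
  ratio, log-normal noise, negative controls, a small strongly
  up-regulated virus panel and planted DE genes concentrated in
  designated categories and gene sets — with exhaustive truth tables.
- **Interface** (`readFasta`, `writeFastq`, `readSignalMatrix`,
  `readGMT`, `readAnnotation`, `pipelineConfig`, `runPipeline`): TSV/GMT/
  FASTA/FASTQ round-trip I/O and a driver that chains
  simulate → merge → platform → de → enrich and emits a reproducibility
  manifest (parameters, seeds, md5 checksums).

## Worked example

```r
library(NovoArray)
cfg <- pipelineConfig(seed = 7, nperm = 500,
    generator = generatorConfig(nTranscripts = 300, depth = 5, seed = 7))
res <- runPipeline(cfg)
```

With this configuration the run prints (via the summaries in `res`):

```
merge: 274 + 32 unique = 306 transcripts (89.2% of secondaries matched, mean identity 99.0)
platform: 299 sequences on array, 295 (98.7%) WABS in all samples, 299 oriented
host DE: 15 up (5.05%), 17 down (5.72%) at adjusted p < 0.05; replicate r = 0.984
     set_id size     ES    NES nominal_p FDR_q
1 apoptosis   30  0.923  2.351     0.000 0.000
2      toll   30 -0.860 -2.196     0.000 0.000
3  jak_stat   30 -0.789 -2.033     0.000 0.000
4       imd   30  0.488  1.276     0.117 0.204
5       jnk   30  0.317  0.823     0.765 0.743
```

Reading this: the merge kept all 274 backbone contigs and added the 32
secondary contigs that had no ≥ 200 bp / ≥ 95 % match (89.2 % of
secondary contigs did match, at 99.0 % mean identity — two assemblers of
the same reads agree closely). Nearly every probed sequence is expressed
well above the negative-control background, every transcript's strand was
called, and the planted 5 % up / 5 % down differential-expression
structure is recovered at adjusted p < 0.05. The GSEA table recovers the
planted gene-set structure: the "apoptosis" set (enriched in up-regulated
genes by construction) has a positive NES at FDR q below the 0.25
decision rule, the two planted down-regulated pathway sets have negative
NES, and the two neutral sets do not pass.

## Vignette

`vignettes/novoarray-methods.Rmd` documents the statistical methods, the
generator's design and defaults, numerical conventions (rounding,
tie-breaks, degenerate inputs) and known limitations.
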