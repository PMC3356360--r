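---
title: "NovoArray methods: from de novo assemblies to a validated expression platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NovoArray methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NovoArray)
```

# Overview

NovoArray models the situation of a transcriptomics study on an organism
without a reference genome: transcripts are assembled de novo from short
reads by two independent assemblers, reconciled into one non-redundant
catalogue, validated on a two-strand oligonucleotide microarray, and the
resulting one-probe-per-gene platform is used for a small-replicate
infection experiment (two infected vs two uninfected cultures) with
empirical-Bayes inference and gene-set enrichment. This vignette explains
each stage's model and assumptions, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

# Assembly reconciliation

## The aligner

All sequence comparisons (assembly-vs-assembly, probe screening, read
mapping) run through one deterministic local aligner: exact 15-mer seeds
are collected on both strands, seeds are grouped by alignment diagonal
(clusters split where diagonals differ by more than twice the band), and
each cluster is extended by banded Smith–Waterman with a linear gap model
(match +1, mismatch −2, gap −3, band half-width 32, report threshold
score ≥ 30). Identity is 100 × matches / alignment columns, with gap
columns in the denominator — the HSP convention of BLAST-style tools.
`N` never seeds and always scores as a mismatch.

Design notes:

- Seeding bounds sensitivity: hits with no exact shared 15-mer are
  invisible. For assembler outputs that differ by scattered substitutions
  at ≤ 2 % this is immaterial (a shared 15-mer occurs every
  ~`1/(1-p)^15` ≈ 16 bases at p = 0.005), and it is the same convention a
  word-size-11+ nucleotide BLAST uses.
- The band (32 diagonals each side of the seed cluster) covers small
  indels; alignments requiring larger excursions would be truncated. The
  test suite verifies score/identity equality against an unbanded
  Smith–Waterman oracle (Biostrings) on substitution-and-small-indel
  instances up to 2 kb.
- Ties between equal-scoring best hits break deterministically: higher
  identity, then longer alignment, then lexicographically smallest target
  id (read mapping instead prefers the smallest reference id, then the
  leftmost position, so multi-mapped reads are counted exactly once).

## Merge rule

Given a backbone (primary) assembly and a secondary assembly, both
length-filtered at 200 bp, a secondary contig is **redundant** iff its
best hit in the primary covers ≥ 200 alignment columns at ≥ 95 %
identity; all other secondary contigs (including no-hit contigs) are
**unique** and are appended to the backbone. The conjunction is applied
to *redundancy*, not to uniqueness: reading the criteria the other way
("unique = shorter than 200 bp **and** below 95 %") would leave a 10 kb,
99 %-identity duplicate neither unique nor redundant, so the only
self-consistent reading is the one implemented. Raising either threshold
can only move contigs from redundant to unique (monotonicity is a tested
property).

## QC conventions

- Mean fold coverage = mean reads per contig × read length / mean contig
  length, **truncated** (not rounded) to one decimal: 651.7 reads of
  100 bp on 1,009 bp contigs gives 64.5×. Truncation is required to
  reproduce that printed arithmetic exactly.
- All other report percentages round half-up (commercial rounding) to one
  decimal (two for the DE summary), matching how such tables are printed.
- N50 is the length of the smallest contig in the minimal set of longest
  contigs covering at least half the assembly's bases.
- A read maps iff its aligned query span is ≥ 95 % of the read length at
  ≥ 90 % identity; each read counts toward a single best position.

# Probe platform

Each transcript receives three 60-mer probes per strand at distinct
uniform-random offsets (sense probes are substrings, antisense probes
reverse complements); transcripts shorter than 62 bp cannot host three
distinct probes and are skipped with a warning. Probes with an off-target
local alignment of ≥ 45 columns at ≥ 90 % identity on any non-parent
transcript are removed as cross-hybridization risks; the source text
gives no thresholds for this screen, so both are explicit, configurable
parameters with defaults chosen at the ¾-of-probe-length / BLAST-megablast
identity scale typical of array QC.

**WABS** ("well above background signal") is undefined in the source
platform beyond its name; NovoArray defines it per sample as intensity
above the negative-control mean plus `kSigma` (default 3) control SDs —
standard one-color practice, monotone in `kSigma` (tested). A transcript
is WABS-in-all-samples if at least one of its probes passes in every
sample, and three-in-one-direction if all three probes of some strand
pass in every sample; strands that lost probes to screening are not
eligible for the three-probe flag, mirroring the "all three probes"
phrasing of the design.

**Orientation** is called per transcript as the strand with the highest
cumulative probe signal, summed over the strand's surviving probes and
over all four samples, on the linear scale. Summing across all samples
uses all the evidence and is symmetric between conditions; because both
strands are rescaled identically by any per-sample factor, the call is
invariant to per-sample positive rescaling (tested). Exact ties go to
the strand with the larger single-probe maximum, then to the
lexicographically smallest probe id. The best probe — the platform's
one-probe-per-gene representative — is the chosen strand's probe with
the highest summed intensity. Transcripts missing probes on either
strand are "undetermined" rather than guessed. Linear-scale intensities
are used for WABS and orientation (background statistics are additive on
the measured scale); logs enter only in the DE stage.

# Differential expression

The virus panel is split from the host panel *before* normalization:
virus genes switch from background to strong signal on infection, which
violates the common-distribution assumption of quantile normalization if
left in. Each panel is transformed as `log2(x + 1)` (the offset guards
zeros; plotted signals are log2 in this field) and quantile-normalized
(Bolstad procedure via limma, ties receiving the mean of their tied-rank
values).

The 2-vs-2 design is fit per gene by ordinary least squares: logFC =
mean(infected) − mean(uninfected), pooled residual variance s² with 2
degrees of freedom. With two replicates per group, per-gene variances are
hopeless on their own; the empirical-Bayes step assumes
s² | σ² ~ σ²·χ²₍df₎/df with a scaled inverse-χ² prior σ² ~ s₀²·df₀/χ²₍df₀₎,
estimating (df₀, s₀²) by matching the mean and variance of log s² to its
theoretical scaled log-F distribution (digamma/trigamma inversion; the
trigamma inverse by Newton iteration). The posterior variance
(df₀ s₀² + df s²)/(df₀ + df) yields a moderated t on df₀ + df degrees of
freedom (capped at the ensemble's pooled df). When the observed
variances are consistent with a single value the prior df is infinite
and every gene uses the common variance — the z-like limit; at df₀ → 0
the statistic reduces to the ordinary t. The implementation is authored
in the package and is verified in the tests against limma's `eBayes` to
10⁻¹⁰ on shared instances, and against closed-form limits.

The log-odds (B) statistic — the natural log of the posterior odds of
differential expression — uses a fixed prior DE proportion of 0.01 and a
fixed prior fold-change variance (default 4 in units of the unscaled
variance ½ + ½). It is reported as a ranking aid only; no calls are made
from it. Calls use Benjamini–Hochberg adjusted p-values at α = 0.05 with
an auxiliary |logFC| > log2(2) sub-classification. The hyperparameters
of the moderated model need an ensemble, so `moderateFit` requires ≥ 10
genes; a virus panel smaller than that is reported descriptively
(fold changes only), which matches its role as a separate, small,
qualitatively different panel.

# Enrichment

- **Delta-proportion score** per category: u/N − d/N, where u and d count
  up- and down-called members and N is the category size. Antisymmetric
  under swapping all labels (tested); a screening statistic, not a test.
- **Hypergeometric over-representation**: one-sided P(X ≥ k) per category
  and direction against the panel universe, BH-adjusted within each
  direction. Testing directions separately matches the practice of
  reporting distinct up- and down-significant categories.
- **Slim roll-up**: a gene counts once per distinct slim class reached by
  any of its terms; multi-class counting is allowed and flagged, so
  percentages are over class assignments, not genes; unmapped terms are
  tallied explicitly.
- **GSEA**: genes ranked by moderated t (descending; the ranking metric
  is the natural product of the DE stage). The running sum adds
  |r|^weight (normalized over set members, weight default 1) at hits and
  subtracts 1/(U − set size) at misses; ES is the signed maximum
  deviation, ties resolved toward the earlier (more extreme) rank. The
  null draws `nperm` (default 1,000) random same-size gene sets — the
  gene-set permutation scheme, appropriate for n = 2 + 2 where sample
  permutation is impossible. NES divides ES by the mean |null ES| of
  matching sign; nominal p is the matching-sign tail fraction; FDR q
  compares each NES to the pooled sign-matched normalized null, divided
  by the observed-NES tail fraction, clipped to [0, 1]. The leading edge
  contains members at or before the peak for positive ES and at or after
  the trough for negative ES (the sign-aware convention of the original
  enrichment framework).

# The synthetic-data generator

The generator defines the study conditions under which everything is
tested. Its defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| length law | log-normal, meanlog = log 1000, sdlog = 0.9, floor 201 bp | median ≈ 1 kb with > 5 % of transcripts beyond 4 kb, the long-tailed shape of filtered de novo assemblies; the floor mirrors the 200 bp length filter already applied to such catalogues |
| virus fraction | 0.005 | a ~135-gene virus panel against a ~27,000-gene host set |
| unique fraction A/B | 0.10 / 0.04 | two same-read assemblers agree on ~90–96 % of sequences |
| substitution rate | 0.005 | scattered per-base disagreements giving ~99 % cross-assembler identity |
| fragmentation / chimera | 0.05 / 0.005 | split and fused contigs as realistic assembly failure modes |
| reads | 100 bp, paired, insert 214 bp, depth 650/transcript | the sequencing design being emulated (one high-depth lane) |
| DE plan | 5 % up + 5 % down at &#124;log2FC&#124; = 2 | a clean planted effect at the platform's own 2-fold reporting threshold |
| antisense ratio | 10 | sense probes ~10× the wrong-strand signal; the source platform reports no measured value — this is a generator convention |
| probe noise | 0.25 (log2 SD) | gives replicate correlations ≈ 0.98–0.99, the regime of good one-color replicates |
| signal / background | log2 means 10 vs 4, SDs 2 / 0.5 | ~6 log2 units of separation makes WABS tunable rather than trivial |
| categories / sets | 40 categories; 5 sets of 30, concentration 0.5 / 0.6 | planted enrichment strong enough to be recoverable, weak enough not to be trivial |

A single master seed derives per-stage substreams (fixed offsets), so
any stage is reproducible in isolation and a fixed seed yields
byte-identical artifacts — the determinism the pipeline manifest checks.

What the generator deliberately does **not** emulate: realistic
sequencer error profiles or quality strings, splice isoforms, probe
thermodynamics (GC/Tm effects on intensity), spatial array artifacts,
and correlated biological variation between replicates. Passing tests
therefore demonstrate that the *algorithms* recover planted structure
under controlled noise, not that the platform's published biological
percentages would be reproduced from raw data — those depend on the real
sequencing and hybridization data. The printed-arithmetic checkpoints
(coverage, merge accounting, report percentages) are exact by
construction; the parameter-recovery statistics (orientation accuracy
≥ 99 %, exact unique-set recovery at zero noise, null type-I error
0.05 ± 0.01, planted gene-set FDR q < 0.25) were calibrated once against
oracle simulations and then frozen.

# Problem sizes and runtime choices

The tests and the acceptance script use scaled-down instances chosen as
the package's own verification sizes: 300–500 transcripts for
orientation/DE/enrichment recovery, 10,000 genes for the null
calibration, ≤ 2 kb pairs for aligner-oracle equivalence, 100–200
simulated gene sets at 150–1,000 permutations for GSEA calibration, and
~70–80-transcript pipelines for manifest determinism. These sizes give
binomial/normal error bars comfortably inside the asserted tolerances
while keeping the whole suite fast on a single CPU.

# Known limitations

- The aligner reports one best local alignment per pair; split/chimeric
  structures surface as a single dominant HSP, not as multi-HSP chains.
- Seeding requires an exact 15-mer; extremely divergent duplicates
  (< ~85 % identity) can escape both the redundancy rule and the
  cross-hybridization screen — conservative for redundancy removal,
  permissive for probe screening.
- The GSEA FDR uses the pooled-null scheme of the original framework,
  whose q-values are conservative for small set collections and can be
  exactly 0 when no null ES exceeds the observed one at the configured
  permutation count.
- `wabs_three_one_direction` requires a full three-probe strand; heavy
  cross-hybridization screening therefore depresses that fraction even
  for well-expressed transcripts.
- With two replicates per group the moderated inference leans on the
  ensemble prior; it is calibrated (tested on a 10,000-gene null) but
  has little power for effects well under 2-fold at the default noise.
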