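Package: NovoArray
Title: Expression Platforms from De Novo Transcriptome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a species-specific expression platform from two de novo
    transcriptome assemblies and analyses host/virus gene expression at early
    baculovirus infection. Provides assembly reconciliation and redundancy
    removal via a deterministic seed-and-extend local aligner, assembly QC
    (length statistics, read-mapping coverage), oligonucleotide probe design
    with cross-hybridization screening, well-above-background (WABS) filtering
    and strand-orientation inference from hybridization signal, two-versus-two
    empirical-Bayes moderated-t differential expression with Benjamini-Hochberg
    correction, delta-proportion category scoring, hypergeometric
    over-representation, GO-slim roll-ups, and weighted running-sum gene-set
    enrichment with permutation-based NES and FDR. A synthetic-data module
    generates transcriptomes, paired assembler outputs, reads and
    probe-intensity matrices with planted ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    limma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
biocViews: Transcriptomics, Microarray, DifferentialExpression,
    GeneSetEnrichment, Sequencing, Software
RoxygenNote: 7.3.3
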