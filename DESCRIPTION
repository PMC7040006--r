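Package: mirfine
Title: Integrative miRNome, Transcriptome and Proteome Analysis of Stem-Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, an integrative
    multi-omics analysis of retinoic-acid induced differentiation of
    umbilical cord blood-derived unrestricted somatic stem cells (USSC):
    counts-per-million normalisation and fold-change/significance filtering
    of mRNA and miRNA sequencing counts, ANOVA/Tukey differential abundance
    for label-free proteomics, mRNA-protein concordance analysis, bipartite
    miRNA-target networks built from multi-algorithm target predictions, and
    the transfection-response crossmatch workflow that quantifies how much
    of the proteome is actually moved by individual miRNAs. A synthetic-data
    generator with known ground truth stands in for the deposited raw data
    so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
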