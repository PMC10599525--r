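Package: codonIO
Title: Codon Initiation-Optimality Enrichment Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Milner", "Bioinformatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-codon log-odds enrichment statistics for studying
    translation initiation optimality in bacteria. Computes 59-element
    log-odds vectors contrasting codon usage between sequence sets
    (transgene expression quartiles, native protein-abundance, noise and
    essentiality strata, 5' windows versus gene cores), with standard
    errors from 2x2 count tables. Provides vector-comparison statistics
    (Pearson/Spearman correlation, PCA orthogonal regression, oriented
    within-block pairwise synonymous differences, exact binomial sign
    tests, multivariate OLS, Cronbach's alpha), a multi-genome
    5'-versus-core survey with GC3 and growth-temperature models, CDS
    ingest from GenBank/EMBL/FASTA with quality filtering, and a
    synthetic-data generator with planted per-codon effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
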