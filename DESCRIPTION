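Package: texpress
Title: Transposable-Element Insertions and Cross-Species Expression Divergence
Version: 0.1.0
Authors@R: person("texpress", "maintainers", email = "texpress@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking transposable-element (TE) insertions to
    interspecific gene-expression differences between two closely related
    nematode species. Implements one-to-one ortholog calling from pairwise
    bitscores (reciprocal best hits with multi-best exclusion), length-corrected
    cross-species normalization with TMM scaling and a negative-binomial exact
    test per developmental stage, gap-statistic k-means clustering of Z-scored
    TPM profiles, strand-aware classification of TE insertion sites into six
    gene-relative regions, conserved-TE calling from boundary-spanning read
    evidence across populations, and Fisher's exact TE-by-expression enrichment
    with Benjamini-Hochberg correction. A synthetic-data generator produces all
    pipeline inputs with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    cluster
Config/testthat/edition: 3
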