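Package: darkome
Title: Dark-Proteome Classification and Comparative Statistics for
    Multi-Taxon Protein Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies proteins of unknown function ("dark" proteins) in
    multi-taxon protein datasets by propagating database-hit evidence over
    homology clusters, partitions dark proteins into high- and
    low-confidence classes, and computes the comparative statistics that
    accompany such surveys: dataset completeness and redundancy QC,
    taxon-pairwise sharing of dark protein families, single-copy ortholog
    selection and supermatrix assembly for phylogenomics, Fisher exact
    enrichment with Benjamini-Hochberg correction and a Gene Ontology
    elimination correction, Robinson-Foulds tree comparison, and a
    resampling test for amino-acid composition differences. Includes a
    synthetic cohort generator with known ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
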