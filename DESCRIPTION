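Package: algkit
Title: Ancestral Linkage Group Macrosynteny, Linkage Conservation, and
    Perturbation Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chromosome-scale comparative genomics and functional
    transcriptomics in non-model animals. Assigns genes to bilaterian
    ancestral linkage groups (ALGs) through single-copy orthology to a
    reference, profiles chromosomes by ALG composition with hypergeometric
    enrichment, and classifies chromosomes as single-ALG, fusions (blockwise
    or mixed, via a runs-based permutation test) or fission products. Tests
    whether focal gene families (e.g. a signalling pathway) retain their ALG
    association more often than a randomized single-copy orthologue
    background using a chi-square test with optional permutation p-value.
    Provides a fixed-dispersion negative-binomial exact test for perturbation
    RNA-seq, direction-consistent classification of pathway-regulated genes
    across inhibitor and ligand arms, cross-stage intersection, and
    transcriptome age index (TAI) contrasts from gene phylostrata. Includes
    seeded synthetic-data generators with planted ground truth for all
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    withr
Config/testthat/edition: 3
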