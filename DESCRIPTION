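Package: serpan
Title: Pan-Genome Association Mapping of Habitat Adaptation in Bacterial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pan-genome environmental-association analysis of
    bacterial strain collections: construction of ortholog groups and gene
    presence/absence matrices from tabular homology hits, core/accessory
    partitioning, SNP calling from core-gene alignments, Nei-Gojobori (1986)
    Ka/Ks estimation, structure-corrected Wilcoxon association mapping of
    gene content and core SNPs against growth phenotypes with Bonferroni and
    FDR control, positional candidate-gene cluster calling on draft contigs,
    a horizontal-transfer distance-shift test on nearest-homolog 16S
    distances, and PERMANOVA-style variance partitioning of genomic distance
    matrices by habitat and geography with bootstrap confidence intervals.
    Includes a synthetic-population generator that emulates a two-habitat,
    multi-reserve rhizobial strain collection with a U-shaped accessory gene
    frequency spectrum, admixture structure, planted habitat-assorting gene
    clusters, and a gene-dropout efficacy simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
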