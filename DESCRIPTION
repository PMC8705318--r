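Package: rhizoxlink
Title: Linking Rhizosphere Microbiome Shifts to Root-Exudate Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating shotgun-metagenome community profiles with
    untargeted root-exudate metabolomes when the two assays were collected on
    different (unpaired) biological replicates. Implements gene-abundance
    quantification with redistribution of multi-mapped reads proportional to
    unique-read abundance, aggregation to taxon and KEGG-ortholog feature
    tables, community diversity and ordination statistics (Hellinger
    transform, Shannon/richness, Bray-Curtis, PCA, one- and two-way PERMANOVA
    via vegan), two-group differential-abundance testing with a relative
    abundance filter and volcano-style classification, and a random-pairing
    resampled Pearson correlation that links differentially abundant taxa to
    differential metabolites with a four-way sign/direction classification.
    A synthetic-data generator reproduces the two-genotype by three-stage
    study design with planted effects and planted condition-mean correlation
    structure so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
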