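Package: mosaicseq
Title: Mosaic Hybrid Genome Analysis: Introgression Scanning, Ancestry
    Classification, Tetrad Genetics and Distance Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference chain for dissecting mosaic yeast genomes assembled
    from several parental Saccharomyces lineages. Detects introgressed
    regions from two-genome comparative hybridization intensities
    (background subtraction, slope normalization, log-ratios, sliding-window
    smoothing, above-background segmentation with sub-kilobase gap merging),
    assigns sequenced markers to parental lineages by pairwise nucleotide
    identity including chimeric-gene breakpoint localization and frameshift
    truncation prediction, analyses tetrad marker segregation (2:2 ratios,
    parental/nonparental ditype classification, exact-binomial independence
    tests, spore viability), builds Kimura 2-parameter neighbor-joining
    trees with bootstrap supports, and clusters strains by microsatellite
    chord distance with midpoint rooting. A seeded synthetic-data generator
    produces three-parent mosaic genomes, replicate array intensities,
    hybrid tetrads and population-structured microsatellite profiles with
    recorded ground truth, so the full pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
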