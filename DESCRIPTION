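Package: satayfit
Title: Comparative Fitness and Lipidomic Adaptation Analysis for
    Saturated Transposon Mutagenesis Screens in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of SAturated Transposon Analysis in Yeast (SATAY)
    screens: reads per-library transposon insertion sites (BED/WIG) and
    gene annotation (GFF3), builds gene-by-library transposon and read
    count matrices, normalizes to sequencing depth, and performs
    library-set volcano comparisons (fold change plus Student's t-test)
    to call conditionally required or dispensable genes. Provides
    variable-gene selection, Ward clustering of libraries, and gene-gene
    Pearson co-essentiality correlation clusterograms. Companion
    lipidomics routines compute fraction-of-total lipid profiles,
    saturation-pair remodeling fractions (cold adaptation of acyl chain
    unsaturation) and stable-isotope labeling flux ratios along the
    PS->PE->PC synthesis chain. A seeded synthetic-data generator
    produces insertion libraries and lipidomes with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
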