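Package: sceScope
Title: Localization and Genomic Interpretation of Sister Chromatid Exchanges
    in Haploid Strand-Seq Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for localizing sister chromatid exchanges (SCEs) in
    haploid single-cell strand-sequencing (Strand-seq) libraries and for
    interpreting their genomic distribution. Reads are filtered by mapping
    quality and duplicate status, isolated strand-flip errors are corrected,
    and changepoints in read directionality are localized by recursive
    binary segmentation with a minimum-support rule. Called SCEs can be
    tested for enrichment or depletion at genomic feature tracks (common
    fragile sites, centromeres, telomeres, gene bodies, G-quadruplex motifs)
    with a gap-aware circular-shift permutation model, scored for hotspot
    clustering with a binomial bin statistic, and related to deletion
    junction microhomology in tumor cohorts stratified by homologous
    recombination status. A fully seeded synthetic-data module generates
    genomes, Strand-seq read tables with planted SCEs, feature tracks with
    controllable enrichment, and deletion cohorts with planted junction
    microhomology, each paired with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: SingleCell, Sequencing, StructuralVariation, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
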