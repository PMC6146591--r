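Package: specklemap
Title: Mapping Nuclear Speckle-Proximal Genomic Regions from RNA-DNA
    Proximity Ligation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for RNA-DNA proximity-ligation (MARGI-style)
    read pairs built around nuclear speckle biology. Classifies chimeric pairs
    by RNA species (spliceosomal snRNAs, 7SK, Malat1, rRNA, posttranscriptional
    pre-mRNA), removes putative nascent-transcript pairs with a genomic distance
    filter, calls broad enrichment domains (nsaPeaks) from sparse DNA-end
    clouds, and validates them with contingency statistics, genome-binned
    density profiles, interval-shuffling permutation tests, TAD boundary
    alignment, and single-cell DNA FISH / SC35 immunofluorescence 3D
    colocalization analysis. A synthetic-data module generates annotated toy
    genomes, pair files under clustered ("speckled") and uniform ("diffuse")
    scenarios with planted truth, and 3D two-channel image stacks, so every
    stage runs and is testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    rtracklayer,
    EBImage,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
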