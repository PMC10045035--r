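Package: svpixel
Title: Image-Based Filtering of Long-Read Structural Variant Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Filters false positives out of merged multi-caller structural
    variant (SV) callsets derived from long-read alignments. Alignment
    signatures around each candidate insertion, deletion, inversion or
    duplication (intra-alignment CIGAR operations and split-read segment
    geometry) are encoded into fixed-size three-channel images, a compact
    convolutional neural network is trained to separate true from false
    calls, and mislabeled negative training samples are eliminated
    beforehand by PCA plus k-means clustering. Translocation records, which
    are never imaged, are merged by a breakpoint-distance rule with a
    caller-support threshold. Includes a synthetic long-read alignment
    simulator so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    VariantAnnotation,
    Biostrings,
    pROC,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralVariation, VariantDetection, Sequencing, Classification
RoxygenNote: 7.3.3
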