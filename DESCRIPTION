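Package: rolony
Title: In Situ Barcode Sequencing Analysis of Single-Neuron Projections
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing in situ sequencing of neuronal RNA barcodes
    (rolonies): spot detection in multi-cycle four-channel image stacks,
    point-cloud registration and tile stitching, base-calling of axonal
    rolonies and somata, Hamming-distance codebook construction and
    error-corrected matching, quality-control filters (floating rolonies,
    secondary infection, overlap deduplication), cortical flatmap
    construction from labeled volumes, projection-based cell typing by
    iterative k-nearest-neighbour label propagation, and single-neuron
    projection statistics (permutation Kolmogorov-Smirnov laminar
    comparisons, focal projection distance, simulated retrograde tracing,
    rolony-linking reconstruction). Includes a ground-truthed synthetic data
    generator emulating barcoded projection neurons of four classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'simulate.R'
    'spots.R'
    'register.R'
    'basecall.R'
    'codebook.R'
    'qc.R'
    'flatmap.R'
    'celltype.R'
    'analysis.R'
    'io.R'
    'rolony-package.R'
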