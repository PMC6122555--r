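Package: hebbsig
Title: Chromatin-Mark Signatures via Unsupervised Hebbian Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a single chromatin-mark signature from thousands of
    same-function genomic regions (promoters, enhancers, coding regions)
    using an unsupervised Hebbian associative network. Regions and ChIP-seq
    peak calls are read from BED files; each region is digitised into a
    marks-by-lines matrix of -1/+1 mark intersections at equally spaced
    vertical lines and flattened into an epigenetic vector. After background
    filtering and consensus denoising, the network's prototype weight vector
    summarises the mark distributions. Signatures are compared with a
    normalised dot product (cosine similarity), per mark or whole-vector,
    directional marks are called from upstream/downstream thirds, and the
    signature is rendered as a red/blue digitised image with mark rows
    ordered by city-block WPGMA hierarchical clustering. A seeded synthetic
    fixture generator emits BED tracks from a planted signature so the whole
    pipeline is testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    png,
    withr,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
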