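Package: genotracks
Title: Server-Side Toolkit for Genomic Track Visualization and Data Services
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A server-side toolkit for building genome-browser style
    visualizations: a columnar genomic data model with readers for BED,
    GFF3, bedGraph and feature-by-sample matrices; interval overlap
    queries; region-binning summarization; cross-sample aggregation and
    hierarchical clustering with dendrograms; linked-brushing resolution
    across coordinated charts; six-column grid layout; deterministic
    static SVG rendering of genes, line, blocks, scatter and heatmap
    charts; a JSON request/response data provider over HTTP; and
    standalone self-contained HTML export. Includes seeded synthetic
    fixture generators for genomes, gene models, signal tracks, peaks
    and expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
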