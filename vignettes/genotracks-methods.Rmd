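---
title: "genotracks: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genotracks: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotracks)
```

`genotracks` is the server-side core of a genome-browser style visualization
stack: it owns the data model, the queries, the summarization, the linking
logic and the rendering, while deliberately leaving interactivity (DOM
events, transitions) out of scope. This vignette explains the science and
the engineering choices; every number shown here is computed by the code in
this package.

## The coordinate model

All coordinates are 0-based half-open `[start, end)`. This is the single
most consequential convention in the package: adjacency and overlap become
unambiguous (`[0,10)` and `[10,20)` share a boundary and do **not**
overlap), interval length is simply `end − start`, and BED/bedGraph input —
the richest dialects consumed here — needs no conversion. GFF3, which is
1-based closed, is converted on read (`start − 1`, `end` unchanged), so an
internal span length equals the GFF `end − start + 1`. Zero-width rows
(`start == end`) denote empty sets and never overlap anything; both the
IRanges-backed index and the brute-force scans agree on this.

Chromosome names are matched exactly — no `"chr1"`/`"1"` aliasing — because
silent aliasing hides upstream data errors. Queries against an unknown
chromosome return empty results rather than erroring, matching how a
browser behaves when a track simply has no data on the current chromosome.

## The columnar data model

A `ColumnTable` is a set of parallel arrays — `chrom`, `start`, `end`, plus
named numeric value columns and optional string side columns — mirroring
the JSON wire format whose required keys are `chr`, `start`, `end` and the
data columns. Missing values are `NA` internally and `null` on the wire,
and survive subsetting and (de)serialization bit-exactly: the serializer
prints 17 significant digits because we found that the default
maximum-precision setting of the JSON layer can lose the final bit of a
double, which broke strict round-trip tests.

Row order is insertion order; anything that answers a query returns rows in
ascending `(start, end, index)` order explicitly, so downstream code never
depends on input file ordering.

## Queries and summarization

`build_index()` groups rows per chromosome into an IRanges nested
containment structure (half-open coordinates shifted to 1-based closed).
The package retains its own linear scan (`rows_in_region()`), and the test
suite holds the two routes equal on thousands of randomized queries.

`summarize_region()` is the provider's workhorse. A region of span *S* is
tiled into `n_bins` contiguous half-open bins; when `S ≥ n_bins` the bin
width is `⌊S / n_bins⌋` with the last bin absorbing the remainder, and for
narrower regions boundaries fall at `⌊b·S/n_bins⌋` so the bins still tile
the region exactly. The default `n_bins = 2000` is the summarization
contract this package inherits and is asserted in the acceptance suite.

A row contributes its value **once to every bin its span intersects**, with
no length weighting. This is the simplest semantics consistent with
"average the values within each interval", and for the common case —
point-like or tile-aligned signal — it coincides with the length-weighted
answer. Where rows straddle bin boundaries and the distinction matters, the
`stat = "wmean"` variant weights each contribution by its overlap length.
Empty bins report count 0 and a `null` value (never an interpolated one),
and per-column counts record non-missing contributions so the
"null iff count 0" invariant holds even with missing data.

`group_overlapping_points()` implements the rendering optimization for
feature plots: each in-region row maps to the pixel column of its interval
midpoint (the anchor coordinate is unspecified upstream; the midpoint is
symmetric and stable under strand), rows sharing a pixel fuse into one
visual object with the group mean as its representative value. Object count
is therefore bounded by plot width, which is what makes brushing and
rendering scale independent of raw row count.

## Aggregation and clustering

`aggregate_columns()` reduces a set of value columns row-wise
(`mean`, `min`, `max`, `sum`, `median` — a deliberate closed list), skipping
missing values; an all-missing row yields a missing result. This is the
tumor-vs-normal workflow: aggregate each group, subtract, plot the
difference.

`hierarchical_cluster()` is written in this package rather than delegating
to `stats::hclust`, for one reason: deterministic tie-breaking. Among
equal-distance candidate pairs, the pair whose lexicographically smallest
member label (then second label) is smallest merges first, and the
smaller-keyed child is drawn left, so dendrograms are reproducible across
platforms and input orderings. Linkage updates follow Lance–Williams
(min / max / size-weighted mean for single / complete / average). The test
suite pins merge heights to a naive O(n³) reference that recomputes
inter-cluster distances from scratch, and to the minimum-spanning-tree
characterization of single linkage. Distances (`euclidean`, `manhattan`,
`1 − Pearson`) wrap the stats primitives; rows with missing entries are
mean-imputed per column first (the upstream material is silent on missing
data; imputation keeps the distance matrix total and is documented
behavior), and a constant row under the correlation metric is an error
rather than a silent `NaN`. Defaults — euclidean distance, complete
linkage — are package decisions, not inherited constants.

Dendrograms serialize to Newick with branch lengths `parent height − child
height`, so root-to-leaf path lengths reproduce merge heights, and to a
nested-JSON form for the renderer.

## Linking and navigation

Brushing resolves against **visual objects**, not raw rows, because feature
plots aggregate: an object is highlighted iff any member row overlaps the
brushed region (half-open). Two consequences are worth stating. First, the
result is independent of the source chart — the event carries only a
region. Second, a highlighted aggregated object may carry member rows that
do not themselves overlap the region; that is the intended object→regions
mapping, and the tests assert the precise form (highlight iff some member
overlaps) rather than a naive subset relation.

Navigation arithmetic: pans shift by `0.2 ×` span, zooms scale the span by
`2` about the midpoint (both configurable; the upstream values are
unstated). Pans clamp at 0 and at the chromosome length when sizes are
known; the span never drops below one base, so zoom-in/zoom-out is an
identity away from the clamps. A collapsed navigation renders only a
chromosome ideogram with its region rectangle and issues **zero** data
queries — enforced by a query counter on the data manager, which also
guarantees that any number of charts sharing a measurement trigger exactly
one underlying table query per region change (data and plots are
separated).

## Rendering

SVG output is a pure function of inputs: fixed margins (40/10/10/20 px),
fixed type defaults (800×100 tracks, 800×400 plots), a fixed categorical
palette keyed by measurement order, and all coordinates printed with two
decimals — identical inputs give byte-identical SVG, which the tests check
literally. Every visual object is one marked element
(`class="visual-object"`, stable id shared with the object map, a
`data-rows` attribute for an optional JS shim). Line tracks break their
polyline at missing bins instead of interpolating; a singleton non-missing
run still counts as a segment. Genes tracks draw span line, exon boxes,
strand arrowheads and labels. Heatmaps draw a measurement × pixel-group
cell grid with a blue–white–red diverging ramp over the visible value
range, ordering rows by the dendrogram's leaf order when one is supplied
and drawing the tree alongside. The ideogram is a plain bar (cytoband
staining needs banding data that is out of scope) with a proportionally
placed highlight rectangle.

For single-measurement scatter plots the x-axis is genomic position
(pixel-grouped); with two measurements the axes are value-vs-value, as in
expression scatter plots. Grouping — and hence brushing — is by genomic
pixel in both cases.

## The provider and offline export

`handle_request()` is a pure function from a request envelope
(`request_id`, `action`, `params`) to a response (`request_id` echoed,
`success`, `payload` or `error`); user errors (unknown datasource,
malformed region) become `success = FALSE`, never an exception. `serve()`
wraps it in a minimal single-threaded HTTP/1.1 POST endpoint on base-R
sockets — a deliberate choice, since no HTTP-server package is in the
guaranteed runtime environment — and the tests hold HTTP responses equal to
in-process calls for every action (transport transparency). Storage is
in-memory from flat files loaded via a JSON config; the original stack's
SQL backend is replaced without changing query semantics. Gene search is
case-insensitive prefix matching.

Offline export writes a single HTML document: charts laid out on the
six-column grid, each cell carrying its SVG and a
`<script type="application/json">` block with the columnar JSON of exactly
the table that was rendered. The export is byte-deterministic, opens with
no network access, and `read_embedded_tables()` recovers the tables — the
round trip is part of the acceptance suite.

## The synthetic world

The fixture generators are first-class, tested code and the only source of
test data. Defaults describe a small but structured world: 3 chromosomes of
1 Mb; a signal track tiled at 1 kb whose values follow a seeded random walk
reflected into [−3, 3] (a bounded walk, not white noise, so line tracks and
summaries show features at every zoom level — emulating methylation or
fold-change signal); 100 non-overlapping scored peaks per chromosome with
exponential widths around 400 bp (ChIP-seq-like); 50 non-overlapping genes
per chromosome with 1–5 exons; and a 100 × 20 expression matrix with a
2-unit shift on half the samples over N(8, 2) baselines with unit noise — a
strong but not caricatural group effect on a log-expression-like scale.
Chromosome counts up to 24 follow the human naming rule
(`chr1..chr22, chrX, chrY`). Every generator is a pure function of the
config (seeds are derived, and the caller's RNG stream is restored), which
is what the byte-determinism criterion tests.

What the generators do **not** emulate: realistic peak shapes, CpG
structure, inter-sample correlation, batch effects, or chromosome-length
heterogeneity. A green test therefore establishes the correctness of the
machinery — parsing, querying, binning arithmetic, clustering, linking,
determinism — not biological realism of any downstream inference.

## Numerical and degenerate-input choices

* Bin boundaries use integer arithmetic; floating point enters only in
  statistics and pixel mapping.
* `value_scale` pads a constant value range by ±0.5 so flat signals render
  mid-panel instead of dividing by zero.
* Empty tables, empty regions, unknown chromosomes, and zero-width rows and
  regions all return empty results, not errors; malformed *input* (ragged
  arrays, `start > end`, non-numeric coordinates) errors with the offending
  column, row, or 1-based line number.
* Navigation clamps rather than errors at chromosome edges.

## Known limitations

* Environment (genome-wide) semantics render against one chromosome's full
  span; there is no concatenated multi-chromosome axis.
* The HTTP provider is sequential; it is correct under bursts because the
  handler is stateless, but it is not a production server (no TLS, CORS, or
  keep-alive).
* BED columns beyond the score, bigWig/tabix-style on-disk indexes, and a
  WebSocket provider are out of scope.
* Heatmap cells aggregate by pixel group before coloring; extremely wide
  regions therefore show group means, not individual features — by design,
  but worth knowing when reading the plot.
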