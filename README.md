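# genotracks

A server-side R toolkit for building genome-browser style visualizations of
functional genomic data. It provides the computational core that interactive
browser front-ends sit on: a columnar genomic data model, interval overlap
queries, region-binning summarization, cross-sample aggregation and
hierarchical clustering with dendrograms, linked-brushing resolution across
coordinated charts, a six-column grid layout, deterministic static SVG
rendering of five chart types, a JSON data-provider service over HTTP, and
standalone self-contained HTML export.

It is aimed at bioinformatics developers who need reproducible track/plot
rendering and data services for epigenomic and expression data (methylation
signal, ChIP-seq peaks and fold change, gene models, expression matrices)
without a database or a JavaScript runtime.

## The model in brief

* **Coordinates** are 0-based half-open `[start, end)` everywhere: adjacent
  intervals share a boundary but never overlap. GFF3 input (1-based closed)
  is converted on read.
* **Columnar data**: a `ColumnTable` holds parallel arrays `chrom`, `start`,
  `end` plus named numeric value columns — the same shape as the JSON wire
  format, whose required keys are `chr`, `start`, `end` and the data
  columns.
* **Summarization**: a query region is tiled into `n_bins` contiguous bins
  (default **2000**) and each value column is reduced per bin
  (`mean`, `min`, `max`, `sum`, `count`, or overlap-length-weighted
  `wmean`). A row contributes once to every bin its span intersects. For a
  region of span *S*, bin *b* covers
  `[start + b·w, start + (b+1)·w)` with `w = ⌊S / n_bins⌋` and the last bin
  absorbing the remainder.
* **Point grouping**: feature plots map each in-region row to the pixel of
  its interval midpoint, `⌊(mid − start)/S · width⌋`, and rows sharing a
  pixel become one visual object (representative value = group mean) — the
  chart never draws more objects than it has pixel columns.
* **Brushing**: a highlighted region lights up a visual object iff any of
  its member rows overlaps the region (half-open); the result is
  independent of which chart initiated the brush.
* **Clustering**: agglomerative hierarchical clustering (single / complete /
  average linkage) over euclidean, manhattan or `1 − Pearson` distances,
  with a deterministic lexicographic tie-break; dendrograms serialize to
  Newick and JSON.
* **Layout**: the grid has six equal columns; track charts span all six,
  feature plots span two, packed left-to-right top-to-bottom.

## Worked example

```r
library(genotracks)

cfg <- fixture_config()                     # seeded synthetic world
sig <- make_signal_track(cfg, "chr1")       # bedGraph text + ground truth
r   <- genomic_range("chr1", 0, 1e6)

bt <- summarize_region(sig$table, r, n_bins = 5)
round(bt$values$signal, 3)
#> [1]  0.910  1.414  0.099 -0.276  0.699
bt$counts$signal
#> [1] 200 200 200 200 200
```

Five bins over a 1 Mb chromosome tiled at 1 kb: each bin averages 200
signal intervals; an empty bin would report count 0 and a `null` value.

```r
layout_assign(list(chart_spec("genes",  "genes_track"),
                   chart_spec("signal", "line_track", "signal"),
                   chart_spec("sc1",    "scatter_plot", "signal"),
                   chart_spec("sc2",    "scatter_plot", "signal")))
#>   chart_id row col_start col_span
#> 1    genes   0         0        6
#> 2   signal   1         0        6
#> 3      sc1   2         0        2
#> 4      sc2   2         2        2
```

Tracks take a full six-column row each; the two scatter plots share row 2.

```r
to_json_columnar(subset_rows(sig$table, 1:2))
#> {"chr":["chr1","chr1"],"start":[0,1000],"end":[1000,2000],
#>  "values":{"signal":[-0.065000000000000002,-1.4171]}}
```

Rendering, serving and exporting:

```r
svg <- render_chart(chart_spec("c1", "line_track", "signal"), sig$table, r)

genome  <- make_genome(cfg)
sources <- list(datasource("signal", tables = list(track = sig$table),
                           seqinfo = genome,
                           measurements = list(measurement("signal",
                             kind = "track", datasource_id = "signal"))))
handle_request(data_request(1, "get_summary",
               list(datasource = "signal", region = "chr1:0-1000000")),
               sources)                      # 2000-bin columnar payload
serve(sources, port = 8000)                  # HTTP JSON endpoint (blocking)
export_standalone_html(list(chart_spec("c1", "line_track", "signal")),
                       sources, r, "page.html")  # offline, self-contained
```

A command-line wrapper lives at `inst/cli/genotracks.R`:

```sh
Rscript inst/cli/genotracks.R make-fixtures --seed 42 --out fixtures/
Rscript inst/cli/genotracks.R summarize --input fixtures/chr1_signal.bedgraph \
    --region chr1:0-1000000 --bins 2000 --stat mean --out bins.json
Rscript inst/cli/genotracks.R serve --config fixtures/sources.json --port 8000
```

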