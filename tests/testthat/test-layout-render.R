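test_that("layout_assign implements the six-column rules", {
  track <- chart_spec("t", "line_track", "m")
  lay1 <- layout_assign(list(track))
  expect_equal(lay1$col_span, 6L)
  expect_equal(lay1$col_start, 0L)

  plots <- lapply(1:4, function(i) chart_spec(paste0("p", i), "scatter_plot", "m"))
  lay4 <- layout_assign(plots)
  expect_equal(lay4$row, c(0L, 0L, 0L, 1L))     # three fit per row
  expect_equal(lay4$col_start, c(0L, 2L, 4L, 0L))
  expect_equal(lay4$col_span, rep(2L, 4))

  expect_error(layout_assign(list(track, track)), "duplicate")
})

test_that("random mixed layouts never overlap and tracks sit alone", {
  set.seed(31)
  types <- c("line_track", "blocks_track", "genes_track", "scatter_plot",
             "heatmap_plot")
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    charts <- lapply(seq_len(n), function(i) {
      ty <- sample(types, 1)
      chart_spec(paste0("c", i), ty,
                 measurement_ids = if (ty == "genes_track") character()
                                   else c("m1", "m2"))
    })
    lay <- layout_assign(charts)
    for (r in unique(lay$row)) {
      rows <- lay[lay$row == r, ]
      expect_lte(sum(rows$col_span), 6)
      # no horizontal overlap
      if (nrow(rows) > 1) {
        o <- order(rows$col_start)
        expect_true(all(rows$col_start[o][-1] >=
                        (rows$col_start + rows$col_span)[o][-nrow(rows)]))
      }
      # a track (span 6) never shares its row
      if (any(rows$col_span == 6)) expect_equal(nrow(rows), 1L)
    }
  }
})

test_that("chart_spec validates measurement arity", {
  expect_error(chart_spec("x", "line_track"), "at least one")
  expect_error(chart_spec("x", "heatmap_plot", "m1"), "at least two")
  expect_silent(chart_spec("x", "genes_track"))
})

test_that("rendering is deterministic and well-formed XML", {
  cfg <- fixture_config(seed = 8)
  sig <- make_signal_track(cfg, "chr1")
  region <- genomic_range("chr1", 0, 100000)
  chart <- chart_spec("c1", "line_track", "signal")
  svg1 <- render_chart(chart, sig$table, region)
  svg2 <- render_chart(chart, sig$table, region)
  expect_identical(svg1, svg2)                  # byte-identical
  expect_silent(xml2::read_xml(svg1))           # well-formed
})

test_that("empty scatter renders axes and zero objects", {
  tab <- make_column_table(values = list(v = double()))
  chart <- chart_spec("s0", "scatter_plot", "v")
  svg <- render_chart(chart, tab, genomic_range("chr1", 0, 1000))
  expect_silent(xml2::read_xml(svg))
  expect_match(svg, 'class="axis"')
  expect_equal(count_visual_objects(svg), 0L)
})

test_that("line track breaks the polyline at null bins", {
  bt <- structure(list(
    region = genomic_range("chr1", 0, 400), n_bins = 4L,
    bin_starts = c(0, 100, 200, 300), bin_ends = c(100, 200, 300, 400),
    values = list(v = c(1, 2, NA, 3)), counts = list(v = c(1, 1, 0, 1)),
    stat = "mean"), class = "BinnedTable")
  chart <- chart_spec("lt", "line_track", "v")
  svg <- render_chart(chart, bt, bt$region)
  # the null bin breaks the line into 2 segments, no interpolation
  segs <- gregexpr("<polyline", svg, fixed = TRUE)[[1]]
  expect_length(segs, 2L)
  expect_equal(count_visual_objects(svg), 3L)   # one per non-null bin

  bt$values$v <- c(1, NA, 2, 3)
  svg2 <- render_chart(chart, bt, bt$region)
  expect_length(gregexpr("<polyline", svg2, fixed = TRUE)[[1]], 2L)
  bt$values$v <- c(1, 2, 3, 4)
  svg3 <- render_chart(chart, bt, bt$region)
  expect_length(gregexpr("<polyline", svg3, fixed = TRUE)[[1]], 1L)
})

test_that("object element counts match the object map across chart types", {
  set.seed(17)
  region <- genomic_range("chr1", 0, 50000)
  tab <- random_table(200, chroms = "chr1", max_pos = 45000, max_width = 30,
                      n_cols = 2)
  scatter <- chart_spec("sc", "scatter_plot", "v1")
  svg <- render_chart(scatter, tab, region, width_px = 120)
  groups <- group_overlapping_points(tab, region, 120)
  expect_equal(count_visual_objects(svg), length(groups))

  blocks <- chart_spec("bl", "blocks_track", "v1")
  svg_b <- render_chart(blocks, tab, region)
  expect_equal(count_visual_objects(svg_b),
               length(rows_in_region(tab, region)))
})

test_that("genes track draws strand arrows, exons and names", {
  g1 <- gene_model("FOXP2", genomic_range("chr1", 1000, 5000), "+",
                   c(1000, 3000), c(1500, 3500))
  g2 <- gene_model("MINUS1", genomic_range("chr1", 8000, 9000), "-")
  chart <- chart_spec("g", "genes_track")
  svg <- render_chart(chart, list(g1, g2), genomic_range("chr1", 0, 10000))
  expect_silent(xml2::read_xml(svg))
  expect_equal(count_visual_objects(svg), 2L)
  expect_length(gregexpr('class="exon"', svg)[[1]], 2L)
  expect_length(gregexpr('class="strand-arrow"', svg)[[1]], 2L)
  expect_match(svg, "FOXP2")
  # out-of-region gene is dropped
  svg2 <- render_chart(chart, list(g1, g2), genomic_range("chr1", 0, 2000))
  expect_equal(count_visual_objects(svg2), 1L)
})

test_that("heatmap renders a cell grid plus dendrogram", {
  cfg <- fixture_config(seed = 15, n_features = 40, n_samples = 4)
  ex <- make_expression(cfg)
  ms <- names(ex$table$values)
  d <- pairwise_distances(
    t(vapply(ms, function(s) ex$table$values[[s]], double(ct_nrow(ex$table)))),
    "euclidean")
  dend <- hierarchical_cluster(d, "complete")
  chart <- chart_spec("hm", "heatmap_plot", ms)
  region <- genomic_range("chr1", 0, 1e6)
  svg <- render_chart(chart, list(table = ex$table, dendrogram = dend), region)
  expect_silent(xml2::read_xml(svg))
  groups <- group_overlapping_points(ex$table, region, 800)
  expect_equal(count_visual_objects(svg), length(groups))
  expect_match(svg, 'class="dendrogram"')
  # row order follows the clustering leaf order
  expect_true(all(vapply(dend$leaf_order, grepl, TRUE, x = svg, fixed = TRUE)))
})

test_that("mismatched data and chart type raise errors", {
  tab <- make_column_table("chr1", 0, 1, values = list(v = 1))
  region <- genomic_range("chr1", 0, 10)
  expect_error(render_chart(chart_spec("g", "genes_track"), tab, region),
               "GeneModel")
  expect_error(render_chart(chart_spec("s", "scatter_plot", "v"),
                            list(1, 2), region), "ColumnTable")
  expect_error(render_chart(chart_spec("l", "line_track", "nope"), tab,
                            region), "nope")
})

test_that("ideogram highlight position is proportional within 1 px", {
  si <- list(chrom = "chr5", length = 1e6)
  full <- render_ideogram(si, genomic_range("chr5", 0, 1e6), width_px = 800)
  expect_match(full, 'class="region-highlight" x="2.00" .* width="796.00"')

  # midpoint quarter-span: x at width/2 - width/8 (bar inset by 2 px)
  mid <- render_ideogram(si, genomic_range("chr5", 375000, 625000), 800)
  x <- as.numeric(sub('.*region-highlight" x="([0-9.]+)".*', "\\1", mid))
  expect_lt(abs(x - (2 + 796 * 0.375)), 1)

  set.seed(6)
  for (rep in 1:10) {
    s <- sample.int(9e5, 1)
    w <- sample.int(1e6 - s, 1)
    svg <- render_ideogram(si, genomic_range("chr5", s, s + w), 800)
    x <- as.numeric(sub('.*region-highlight" x="([0-9.]+)".*', "\\1", svg))
    wd <- as.numeric(sub('.*region-highlight" x="[0-9.]+" y="6" width="([0-9.]+)".*',
                         "\\1", svg))
    expect_lt(abs((x - 2) / 796 - s / 1e6), 1 / 796)
    expect_lt(abs(wd / 796 - w / 1e6), 2 / 796 + 1e-9)
  }
  expect_error(render_ideogram(si, genomic_range("chr5", 0, 2e6)), "outside")
  expect_error(render_ideogram(si, genomic_range("chr1", 0, 10)), "outside")
})
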