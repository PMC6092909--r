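#' Static SVG chart rendering
#'
#' Deterministic, dependency-free SVG 1.1 output for the five chart types.
#' Rendering is a pure function: identical inputs and settings produce
#' byte-identical SVG. Every visual object carries a stable `id` attribute
#' (`<chart_id>-obj-<k>`, matching [build_object_map()]) plus a
#' `data-rows` attribute listing its member rows, so a thin JS shim could
#' re-attach interactivity, but interactivity is not part of the contract.
#'
#' Fixed documented defaults: 800x100 px tracks, 800x400 px plots,
#' margins 40 left / 10 right / 10 top / 20 bottom, categorical palette
#' keyed by measurement order.
#'
#' @name rendering
NULL

PALETTE <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
             "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")

fmt_px <- function(x) formatC(x, format = "f", digits = 2)

svg_open <- function(width, height) {
  paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
         width, '" height="', height, '" viewBox="0 0 ', width, " ", height,
         '">')
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

chart_margins <- function() list(left = 40, right = 10, top = 10, bottom = 20)

# linear genome -> pixel map over the drawable area
gx <- function(pos, region, width) {
  m <- chart_margins()
  m$left + (pos - region$start) / range_span(region) * (width - m$left - m$right)
}

axis_elements <- function(region, width, height, ylim = NULL) {
  m <- chart_margins()
  x0 <- m$left; x1 <- width - m$right
  y0 <- height - m$bottom; y1 <- m$top
  out <- c(
    paste0('<line class="axis" x1="', fmt_px(x0), '" y1="', fmt_px(y0),
           '" x2="', fmt_px(x1), '" y2="', fmt_px(y0),
           '" stroke="#333333" stroke-width="1"/>'),
    paste0('<text class="axis-label" x="', fmt_px(x0), '" y="',
           fmt_px(height - 5), '" font-size="10" fill="#333333">',
           xml_escape(format(region, scientific = FALSE)), "</text>"))
  if (!is.null(ylim)) {
    out <- c(out,
      paste0('<line class="axis" x1="', fmt_px(x0), '" y1="', fmt_px(y0),
             '" x2="', fmt_px(x0), '" y2="', fmt_px(y1),
             '" stroke="#333333" stroke-width="1"/>'),
      paste0('<text class="axis-label" x="2" y="', fmt_px(y1 + 8),
             '" font-size="10" fill="#333333">',
             fmt_px(ylim[2]), "</text>"),
      paste0('<text class="axis-label" x="2" y="', fmt_px(y0),
             '" font-size="10" fill="#333333">',
             fmt_px(ylim[1]), "</text>"))
  }
  out
}

value_scale <- function(values, height) {
  m <- chart_margins()
  rng <- suppressWarnings(range(values, na.rm = TRUE, finite = TRUE))
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  list(lim = rng,
       map = function(v) {
         (height - m$bottom) -
           (v - rng[1]) / (rng[2] - rng[1]) * (height - m$bottom - m$top)
       })
}

obj_attr <- function(chart_id, k, rows) {
  paste0('id="', chart_id, "-obj-", k, '" class="visual-object" data-rows="',
         paste(rows, collapse = ","), '"')
}

#' Render a chart to SVG text
#'
#' @param chart A [chart_spec()].
#' @param data Chart-type dependent: `ColumnTable` for line/blocks tracks
#'   and scatter plots; `BinnedTable` also accepted for line tracks
#'   (summarized path); a list of [gene_model()] for genes tracks; for
#'   heatmaps a `ColumnTable` or `list(table = , dendrogram = )`.
#' @param region The [genomic_range()] in view.
#' @param width_px,height_px Output size in pixels; `height_px = NULL`
#'   picks the type default (100 for tracks, 400 for plots).
#' @return A single string of SVG markup.
#' @export
render_chart <- function(chart, data, region, width_px = 800,
                         height_px = NULL) {
  stopifnot(inherits(chart, "ChartSpec"), inherits(region, "GenomicRange"))
  if (range_span(region) <= 0) stop("region must have end > start", call. = FALSE)
  if (is.null(height_px)) {
    height_px <- if (is_track_type(chart$chart_type)) 100 else 400
  }
  body <- switch(chart$chart_type,
    line_track = render_line_track(chart, data, region, width_px, height_px),
    blocks_track = render_blocks_track(chart, data, region, width_px, height_px),
    genes_track = render_genes_track(chart, data, region, width_px, height_px),
    scatter_plot = render_scatter(chart, data, region, width_px, height_px),
    heatmap_plot = render_heatmap(chart, data, region, width_px, height_px))
  paste(c(svg_open(width_px, height_px),
          paste0('<g class="chart" data-chart-id="', chart$chart_id,
                 '" data-chart-type="', chart$chart_type, '">'),
          body, "</g>", "</svg>"), collapse = "\n")
}

require_table <- function(data, chart) {
  if (!inherits(data, "ColumnTable")) {
    stop("chart '", chart$chart_id, "' (", chart$chart_type,
         ") requires a ColumnTable, got ", class(data)[1L], call. = FALSE)
  }
  data
}

line_track_points <- function(data, region, chart) {
  # returns x positions, y values (NA = gap) and member rows per point
  if (inherits(data, "BinnedTable")) {
    col <- if (length(chart$measurement_ids)) chart$measurement_ids[1L]
           else names(data$values)[1L]
    if (is.null(data$values[[col]])) {
      stop("measurement '", col, "' not in binned data", call. = FALSE)
    }
    list(mid = (data$bin_starts + data$bin_ends) / 2,
         val = data$values[[col]],
         rows = seq_len(data$n_bins))
  } else {
    data <- require_table(data, chart)
    col <- if (length(chart$measurement_ids)) chart$measurement_ids[1L]
           else names(data$values)[1L]
    if (is.null(data$values[[col]])) {
      stop("measurement '", col, "' not in data", call. = FALSE)
    }
    rows <- rows_in_region(data, region)
    list(mid = (data$start[rows] + data$end[rows]) / 2,
         val = data$values[[col]][rows],
         rows = rows)
  }
}

render_line_track <- function(chart, data, region, width, height) {
  if (!inherits(data, "ColumnTable") && !inherits(data, "BinnedTable")) {
    stop("line_track requires a ColumnTable or BinnedTable", call. = FALSE)
  }
  pts <- line_track_points(data, region, chart)
  keep <- !is.na(pts$val)
  sc <- value_scale(pts$val, height)
  out <- axis_elements(region, width, height, sc$lim)
  color <- chart$settings$color %||% PALETTE[1L]
  # polyline segments broken at missing values (no interpolation across gaps)
  if (any(keep)) {
    runs <- rle(keep)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    # one polyline per maximal non-missing run; a singleton run still counts
    # as a segment (its mark is the circle below)
    for (r in which(runs$values)) {
      seg <- starts[r]:stops[r]
      coords <- paste(fmt_px(gx(pts$mid[seg], region, width)),
                      fmt_px(sc$map(pts$val[seg])), sep = ",",
                      collapse = " ")
      out <- c(out, paste0('<polyline class="line-segment" points="',
                           coords, '" fill="none" stroke="', color,
                           '" stroke-width="1.5"/>'))
    }
  }
  idx <- which(keep)
  if (length(idx)) {
    out <- c(out, paste0(
      '<circle ', vapply(seq_along(idx), function(j) {
        obj_attr(chart$chart_id, j, pts$rows[idx[j]])
      }, ""), ' cx="', fmt_px(gx(pts$mid[idx], region, width)),
      '" cy="', fmt_px(sc$map(pts$val[idx])), '" r="1.5" fill="', color,
      '"/>'))
  }
  out
}

render_blocks_track <- function(chart, data, region, width, height) {
  data <- require_table(data, chart)
  rows <- rows_in_region(data, region)
  m <- chart_margins()
  out <- axis_elements(region, width, height)
  color <- chart$settings$color %||% PALETTE[1L]
  if (length(rows)) {
    x0 <- gx(pmax(data$start[rows], region$start), region, width)
    x1 <- gx(pmin(data$end[rows], region$end), region, width)
    y <- m$top + 10
    h <- height - m$top - m$bottom - 20
    out <- c(out, paste0(
      '<rect ', vapply(seq_along(rows), function(k) {
        obj_attr(chart$chart_id, k, rows[k])
      }, ""), ' x="', fmt_px(x0), '" y="', fmt_px(y),
      '" width="', fmt_px(pmax(x1 - x0, 1)), '" height="', fmt_px(h),
      '" fill="', color, '" fill-opacity="0.7"/>'))
  }
  out
}

render_genes_track <- function(chart, data, region, width, height) {
  if (!is.list(data) || (length(data) && !inherits(data[[1L]], "GeneModel"))) {
    stop("genes_track requires a list of GeneModel objects", call. = FALSE)
  }
  keep <- vapply(data, function(g) ranges_overlap(g$range, region), TRUE)
  genes <- data[keep]
  m <- chart_margins()
  out <- axis_elements(region, width, height)
  mid_y <- (m$top + height - m$bottom) / 2
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    x0 <- gx(max(g$range$start, region$start), region, width)
    x1 <- gx(min(g$range$end, region$end), region, width)
    parts <- paste0('<line x1="', fmt_px(x0), '" y1="', fmt_px(mid_y),
                    '" x2="', fmt_px(x1), '" y2="', fmt_px(mid_y),
                    '" stroke="#444444" stroke-width="1"/>')
    for (j in seq_along(g$exon_starts)) {
      ex0 <- gx(max(g$exon_starts[j], region$start), region, width)
      ex1 <- gx(min(g$exon_ends[j], region$end), region, width)
      if (ex1 <= ex0) next
      parts <- c(parts, paste0(
        '<rect class="exon" x="', fmt_px(ex0), '" y="', fmt_px(mid_y - 6),
        '" width="', fmt_px(ex1 - ex0), '" height="12" fill="#3366cc"/>'))
    }
    if (g$strand %in% c("+", "-")) {
      tip <- if (g$strand == "+") x1 else x0
      dir <- if (g$strand == "+") -6 else 6
      parts <- c(parts, paste0(
        '<path class="strand-arrow" d="M ', fmt_px(tip), " ", fmt_px(mid_y),
        " L ", fmt_px(tip + dir), " ", fmt_px(mid_y - 4),
        " L ", fmt_px(tip + dir), " ", fmt_px(mid_y + 4),
        ' Z" fill="#444444"/>'))
    }
    parts <- c(parts, paste0(
      '<text x="', fmt_px(x0), '" y="', fmt_px(mid_y - 10),
      '" font-size="9" fill="#222222">', xml_escape(g$gene_name), "</text>"))
    out <- c(out, paste0('<g ', obj_attr(chart$chart_id, k, which(keep)[k]),
                         ">"), parts, "</g>")
  }
  out
}

render_scatter <- function(chart, data, region, width, height) {
  data <- require_table(data, chart)
  ms <- chart$measurement_ids
  missing_ms <- setdiff(ms, names(data$values))
  if (length(missing_ms)) {
    stop("measurement '", missing_ms[1L], "' not in data", call. = FALSE)
  }
  groups <- group_overlapping_points(data, region, width)
  two_d <- length(ms) >= 2L
  yvals <- vapply(groups, function(g) g$values[[ms[1L]]], 0)
  out <- character()
  color <- chart$settings$color %||% PALETTE[1L]
  r <- chart$settings$point_size %||% 3
  if (two_d) {
    xvals <- vapply(groups, function(g) g$values[[ms[1L]]], 0)
    yvals <- vapply(groups, function(g) g$values[[ms[2L]]], 0)
    sx <- value_scale(xvals, width)   # reuse vertical scale math, then flip
    sy <- value_scale(yvals, height)
    m <- chart_margins()
    mapx <- function(v) {
      m$left + (v - sx$lim[1]) / (sx$lim[2] - sx$lim[1]) *
        (width - m$left - m$right)
    }
    out <- axis_elements(region, width, height, sy$lim)
    for (k in seq_along(groups)) {
      if (is.na(xvals[k]) || is.na(yvals[k])) next
      out <- c(out, paste0(
        '<circle ', obj_attr(chart$chart_id, k, groups[[k]]$rows),
        ' cx="', fmt_px(mapx(xvals[k])), '" cy="', fmt_px(sy$map(yvals[k])),
        '" r="', r, '" fill="', color, '" fill-opacity="0.6"/>'))
    }
  } else {
    sy <- value_scale(yvals, height)
    out <- axis_elements(region, width, height, sy$lim)
    span <- range_span(region)
    for (k in seq_along(groups)) {
      if (is.na(yvals[k])) next
      px <- chart_margins()$left + (groups[[k]]$pixel_x + 0.5) / width *
        (width - chart_margins()$left - chart_margins()$right)
      out <- c(out, paste0(
        '<circle ', obj_attr(chart$chart_id, k, groups[[k]]$rows),
        ' cx="', fmt_px(px), '" cy="', fmt_px(sy$map(yvals[k])),
        '" r="', r, '" fill="', color, '" fill-opacity="0.6"/>'))
    }
  }
  out
}

heat_color <- function(v, lim) {
  if (is.na(v)) return("#dddddd")
  t <- (v - lim[1]) / (lim[2] - lim[1])
  t <- min(max(t, 0), 1)
  # blue -> white -> red diverging ramp
  if (t < 0.5) {
    f <- t / 0.5
    rgb_hex(round(59 + f * (255 - 59)), round(76 + f * (255 - 76)), 192)
  } else {
    f <- (t - 0.5) / 0.5
    rgb_hex(255, round(255 - f * (255 - 64)), round(192 - f * (192 - 60)))
  }
}

rgb_hex <- function(r, g, b) sprintf("#%02x%02x%02x", r, g, b)

render_heatmap <- function(chart, data, region, width, height) {
  dend <- NULL
  if (is.list(data) && !inherits(data, "ColumnTable")) {
    dend <- data$dendrogram
    data <- data$table
  }
  data <- require_table(data, chart)
  ms <- chart$measurement_ids
  missing_ms <- setdiff(ms, names(data$values))
  if (length(missing_ms)) {
    stop("measurement '", missing_ms[1L], "' not in data", call. = FALSE)
  }
  if (!is.null(dend)) {
    stopifnot(inherits(dend, "Dendrogram"))
    ms <- dend$leaf_order   # row order follows the clustering
  }
  m <- chart_margins()
  dend_w <- if (is.null(dend)) 0 else 60
  groups <- group_overlapping_points(data, region, width)
  out <- axis_elements(region, width, height)
  n_rows <- length(ms)
  plot_x0 <- m$left + dend_w
  plot_w <- width - plot_x0 - m$right
  plot_y0 <- m$top
  plot_h <- height - m$top - m$bottom
  row_h <- plot_h / n_rows
  all_vals <- unlist(lapply(groups, function(g) g$values[ms]), use.names = FALSE)
  lim <- range(all_vals, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(lim))) lim <- c(0, 1)
  if (lim[1] == lim[2]) lim <- lim + c(-0.5, 0.5)
  cell_w <- if (length(groups)) plot_w / length(groups) else plot_w
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    cells <- vapply(seq_along(ms), function(ri) {
      paste0('<rect x="', fmt_px(plot_x0 + (k - 1) * cell_w),
             '" y="', fmt_px(plot_y0 + (ri - 1) * row_h),
             '" width="', fmt_px(cell_w), '" height="', fmt_px(row_h),
             '" fill="', heat_color(g$values[[ms[ri]]], lim), '"/>')
    }, "")
    out <- c(out, paste0('<g ', obj_attr(chart$chart_id, k, g$rows), ">"),
             cells, "</g>")
  }
  for (ri in seq_along(ms)) {
    out <- c(out, paste0(
      '<text x="', fmt_px(width - m$right + 1), '" y="',
      fmt_px(plot_y0 + (ri - 0.5) * row_h + 3),
      '" font-size="8" fill="#222222">', xml_escape(ms[ri]), "</text>"))
  }
  if (!is.null(dend)) {
    out <- c(out, render_dendrogram_svg(dend, x0 = m$left, x1 = plot_x0,
                                        y0 = plot_y0, row_h = row_h))
  }
  out
}

render_dendrogram_svg <- function(dend, x0, x1, y0, row_h) {
  max_h <- max(dend$height)
  if (max_h <= 0) max_h <- 1
  leaf_y <- stats::setNames(y0 + (seq_along(dend$leaf_order) - 0.5) * row_h,
                            dend$leaf_order)
  hx <- function(h) x1 - h / max_h * (x1 - x0)
  out <- character()
  node_pos <- function(id) {
    if (id < 0L) return(c(hx(0), leaf_y[[dend$labels[-id]]]))
    kids <- dend$left_right[id, ]
    p1 <- node_pos(kids[1L]); p2 <- node_pos(kids[2L])
    x <- hx(dend$height[id])
    out <<- c(out,
      paste0('<path class="dendrogram" d="M ', fmt_px(p1[1]), " ",
             fmt_px(p1[2]), " H ", fmt_px(x), " V ", fmt_px(p2[2]),
             " H ", fmt_px(p2[1]), '" fill="none" stroke="#555555" stroke-width="1"/>'))
    c(x, (p1[2] + p2[2]) / 2)
  }
  node_pos(nrow(dend$merge))
  out
}

#' Render a chromosome ideogram with a highlighted region
#'
#' The collapsed-navigation view: a plain chromosome bar (no cytoband
#' staining; banding data is out of scope) with a yellow rectangle marking
#' the navigation's region, positioned proportionally to the chromosome
#' length.
#'
#' @param chrom_info One row of a [seq_info()] table (`chrom`, `length`),
#'   or a list with those fields.
#' @param highlight A [genomic_range()] within the chromosome.
#' @param width_px Output width (height is fixed at 30).
#' @return SVG text.
#' @export
render_ideogram <- function(chrom_info, highlight, width_px = 800) {
  stopifnot(inherits(highlight, "GenomicRange"))
  len <- as.double(chrom_info$length)
  chrom <- as.character(chrom_info$chrom)
  stopifnot(length(len) == 1L, length(chrom) == 1L)
  if (highlight$chrom != chrom || highlight$start < 0 || highlight$end > len) {
    stop("highlight outside chromosome ", chrom, call. = FALSE)
  }
  height <- 30
  bar_x0 <- 2; bar_w <- width_px - 4
  px <- function(pos) bar_x0 + pos / len * bar_w
  paste(c(
    svg_open(width_px, height),
    paste0('<rect class="chromosome-bar" x="', fmt_px(bar_x0),
           '" y="8" width="', fmt_px(bar_w),
           '" height="14" rx="7" fill="#e8e8e8" stroke="#888888"/>'),
    paste0('<rect class="region-highlight" x="', fmt_px(px(highlight$start)),
           '" y="6" width="', fmt_px(pmax(px(highlight$end) - px(highlight$start), 1)),
           '" height="18" fill="#ffd700" fill-opacity="0.8" stroke="#b8860b"/>'),
    paste0('<text x="', fmt_px(bar_x0), '" y="6" font-size="9" fill="#222222">',
           xml_escape(chrom), "</text>"),
    "</svg>"), collapse = "\n")
}
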