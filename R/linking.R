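#' Brush event
#'
#' A highlighted genomic region originating from one chart, to be
#' propagated to every linked chart in the workspace.
#'
#' @param source_chart_id Chart the highlight originated from.
#' @param region A [genomic_range()].
#' @return An object of class `BrushEvent`.
#' @export
brush_event <- function(source_chart_id, region) {
  stopifnot(is.character(source_chart_id), length(source_chart_id) == 1L,
            inherits(region, "GenomicRange"))
  structure(list(source_chart_id = source_chart_id, region = region),
            class = "BrushEvent")
}

#' Map data rows to the visual objects of one chart
#'
#' Brushing resolves against visual objects, not raw rows, because feature
#' plots aggregate overlapping points into a single mark. Track charts get
#' one object per in-region row; feature plots (scatter, heatmap) get one
#' object per pixel group from [group_overlapping_points()], each carrying
#' all member rows. Object ids are stable (`<chart_id>-obj-<k>`) so SVG
#' elements and brush resolution refer to the same thing.
#'
#' @param chart A [chart_spec()].
#' @param tab The chart's `ColumnTable`.
#' @param region Region in view.
#' @param width_px Plot width in pixels (feature plots only).
#' @return An object of class `ObjectMap` entry: list of objects, each with
#'   `object_id` and `rows`; attribute `chart_id`.
#' @export
build_object_map <- function(chart, tab, region, width_px = 800) {
  stopifnot(inherits(chart, "ChartSpec"), inherits(tab, "ColumnTable"),
            inherits(region, "GenomicRange"))
  if (is_track_type(chart$chart_type)) {
    rows <- rows_in_region(tab, region)
    objects <- lapply(seq_along(rows), function(k) {
      list(object_id = paste0(chart$chart_id, "-obj-", k), rows = rows[k])
    })
  } else {
    groups <- group_overlapping_points(tab, region, width_px)
    objects <- lapply(seq_along(groups), function(k) {
      list(object_id = paste0(chart$chart_id, "-obj-", k),
           rows = groups[[k]]$rows)
    })
  }
  structure(objects, chart_id = chart$chart_id, class = "ObjectMap")
}

#' Resolve a brush event across charts
#'
#' A visual object lights up iff any of its member rows' half-open ranges
#' overlaps the event region; adjacent regions sharing only a boundary do
#' not co-highlight, and charts whose data lie on other chromosomes get an
#' empty highlight set. The source chart is resolved like any other, so the
#' result does not depend on which chart initiated the brush.
#'
#' @param event A [brush_event()].
#' @param maps Named list of [build_object_map()] results (one per chart).
#' @param tables Named list of `ColumnTable`s, parallel to `maps`.
#' @return Named list: chart id -> character vector of highlighted object ids.
#' @export
resolve_brush <- function(event, maps, tables) {
  stopifnot(inherits(event, "BrushEvent"))
  region <- event$region
  out <- list()
  for (chart_id in names(maps)) {
    map <- maps[[chart_id]]
    tab <- tables[[chart_id]]
    hit_rows <- rows_in_region(tab, region)
    hits <- character()
    if (length(hit_rows)) {
      mark <- logical(ct_nrow(tab))
      mark[hit_rows] <- TRUE
      for (obj in map) {
        if (any(mark[obj$rows])) hits <- c(hits, obj$object_id)
      }
    }
    out[[chart_id]] <- hits
  }
  out
}

#' Pan or zoom a genomic region
#'
#' Standard genome-browser navigation arithmetic. Panning shifts by
#' `step_fraction * span` and clamps at position 0 (and at the chromosome
#' length when `seqinfo` is supplied). Zooming scales the span by
#' `zoom_factor` (out) or `1 / zoom_factor` (in) about the midpoint; the
#' span never drops below one base, so zoom-in followed by zoom-out with
#' the same factor is the identity away from the clamps.
#'
#' @param region A [genomic_range()].
#' @param action `"pan_left"`, `"pan_right"`, `"zoom_in"` or `"zoom_out"`.
#' @param step_fraction Pan step as a fraction of the span (default 0.2).
#' @param zoom_factor Zoom ratio (default 2).
#' @param seqinfo Optional [seq_info()] for right-edge clamping.
#' @return The new [genomic_range()].
#' @export
navigate <- function(region, action = c("pan_left", "pan_right",
                                        "zoom_in", "zoom_out"),
                     step_fraction = 0.2, zoom_factor = 2, seqinfo = NULL) {
  action <- match.arg(action)
  stopifnot(inherits(region, "GenomicRange"))
  span <- range_span(region)
  chrom_len <- Inf
  if (!is.null(seqinfo)) {
    row <- match(region$chrom, seqinfo$chrom)
    if (!is.na(row)) chrom_len <- seqinfo$length[row]
  }
  if (action %in% c("pan_left", "pan_right")) {
    step <- round(step_fraction * span)
    shift <- if (action == "pan_left") -step else step
    new_start <- region$start + shift
    new_start <- min(max(new_start, 0), max(chrom_len - span, 0))
    return(genomic_range(region$chrom, new_start, new_start + span))
  }
  mid <- (region$start + region$end) / 2
  new_span <- if (action == "zoom_out") span * zoom_factor else span / zoom_factor
  new_span <- max(round(new_span), 1)
  new_start <- round(mid - new_span / 2)
  new_start <- max(new_start, 0)
  new_end <- new_start + new_span
  if (new_end > chrom_len) {
    new_end <- chrom_len
    new_start <- max(new_end - new_span, 0)
  }
  genomic_range(region$chrom, new_start, new_end)
}
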