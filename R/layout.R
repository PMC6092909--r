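#' Declarative chart description
#'
#' A chart is described separately from its data: the type, the
#' measurements it draws, and cosmetic settings. Five chart types are
#' supported — three track-based (aligned to genome coordinates, full
#' layout width) and two feature-based (scatter, heatmap).
#'
#' @param chart_id Unique chart identifier.
#' @param chart_type One of `"genes_track"`, `"line_track"`,
#'   `"blocks_track"`, `"scatter_plot"`, `"heatmap_plot"`.
#' @param measurement_ids Measurement ids drawn by this chart. Track types
#'   need at least one (genes tracks excepted); heatmaps need at least two
#'   so clustering is defined.
#' @param settings Named list of settings (colors, point size, row height);
#'   unspecified settings fall back to fixed documented defaults.
#' @param region_bound Optional [genomic_range()] pinning the chart to a
#'   region (navigation semantics); `NULL` means genome-wide (environment
#'   semantics).
#' @return An object of class `ChartSpec`.
#' @export
chart_spec <- function(chart_id,
                       chart_type = c("genes_track", "line_track",
                                      "blocks_track", "scatter_plot",
                                      "heatmap_plot"),
                       measurement_ids = character(), settings = list(),
                       region_bound = NULL) {
  chart_type <- match.arg(chart_type)
  stopifnot(is.character(chart_id), length(chart_id) == 1L, nzchar(chart_id))
  if (chart_type %in% c("line_track", "blocks_track", "scatter_plot") &&
      length(measurement_ids) < 1L) {
    stop(chart_type, " requires at least one measurement", call. = FALSE)
  }
  if (chart_type == "heatmap_plot" && length(measurement_ids) < 2L) {
    stop("heatmap_plot requires at least two measurements", call. = FALSE)
  }
  if (!is.null(region_bound)) stopifnot(inherits(region_bound, "GenomicRange"))
  structure(list(chart_id = chart_id, chart_type = chart_type,
                 measurement_ids = as.character(measurement_ids),
                 settings = settings, region_bound = region_bound),
            class = "ChartSpec")
}

is_track_type <- function(chart_type) {
  chart_type %in% c("genes_track", "line_track", "blocks_track")
}

#' Assign charts to the grid layout
#'
#' The workspace grid splits the available width into six equal columns
#' (configurable). Track-based charts extend across all columns; plot-based
#' charts span two. Charts are packed left-to-right, top-to-bottom in input
#' order; a chart that does not fit on the current row starts a new one, so
#' a track always has a row to itself.
#'
#' @param charts List of [chart_spec()] objects with unique ids.
#' @param total_columns Number of grid columns (default 6).
#' @return A data.frame with columns `chart_id`, `row`, `col_start`,
#'   `col_span` (row/col 0-based).
#' @export
layout_assign <- function(charts, total_columns = 6L) {
  total_columns <- as.integer(total_columns)
  stopifnot(total_columns >= 2L)
  ids <- vapply(charts, `[[`, "", "chart_id")
  if (anyDuplicated(ids)) {
    stop("duplicate chart id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  plot_span <- 2L
  row <- 0L
  col <- 0L
  out <- vector("list", length(charts))
  for (i in seq_along(charts)) {
    span <- if (is_track_type(charts[[i]]$chart_type)) total_columns else plot_span
    if (col + span > total_columns) {
      row <- row + 1L
      col <- 0L
    }
    out[[i]] <- data.frame(chart_id = ids[i], row = row,
                           col_start = col, col_span = span,
                           stringsAsFactors = FALSE)
    col <- col + span
    if (col >= total_columns) {
      row <- row + 1L
      col <- 0L
    }
  }
  do.call(rbind, out)
}
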