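#' Shared data manager with per-region query caching
#'
#' Data and plots are separated: charts never query on their own; a
#' workspace fetches through this manager, which issues at most one
#' underlying table query per (datasource, kind, region) no matter how many
#' charts share a measurement, and counts every underlying query so the
#' separation is testable.
#'
#' @param sources List of [datasource()] objects.
#' @return An environment of class `DataManager` with fields `sources`,
#'   `cache` and `query_count`.
#' @export
data_manager <- function(sources) {
  dm <- new.env(parent = emptyenv())
  dm$sources <- sources
  dm$cache <- new.env(parent = emptyenv())
  dm$query_count <- 0L
  class(dm) <- "DataManager"
  dm
}

#' Fetch in-region rows through the data manager
#'
#' @param dm A [data_manager()].
#' @param datasource_id Datasource id.
#' @param kind Table kind, `"track"` or `"feature"`.
#' @param region A [genomic_range()], or `NULL` for the whole table
#'   (environment semantics: genome-wide data).
#' @return A `ColumnTable`.
#' @export
dm_get_rows <- function(dm, datasource_id, kind, region = NULL) {
  stopifnot(inherits(dm, "DataManager"))
  key <- paste(datasource_id, kind,
               if (is.null(region)) "genome-wide" else format(region),
               sep = "|")
  hit <- get0(key, envir = dm$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  src <- find_source(dm$sources, datasource_id)
  if (is.null(src)) stop("unknown datasource: ", datasource_id, call. = FALSE)
  tab <- src$tables[[kind]]
  if (is.null(tab)) stop("datasource '", datasource_id, "' has no '", kind,
                         "' table", call. = FALSE)
  dm$query_count <- dm$query_count + 1L
  out <- if (is.null(region)) tab else subset_rows(tab, rows_in_region(tab, region))
  assign(key, out, envir = dm$cache)
  out
}

#' Reset the manager cache (e.g. on a region change)
#' @param dm A [data_manager()].
#' @return The manager, invisibly.
#' @export
dm_reset <- function(dm) {
  stopifnot(inherits(dm, "DataManager"))
  dm$cache <- new.env(parent = emptyenv())
  invisible(dm)
}

#' Workspace: charts plus navigation state
#'
#' A navigation binds its charts to one region with pan/zoom; when
#' `collapsed`, only the chromosome ideogram is drawn and no data queries
#' are issued for its charts. Charts with no `region_bound` and a `NULL`
#' workspace region follow environment semantics (genome-wide data).
#'
#' @param charts List of [chart_spec()] objects.
#' @param region Optional [genomic_range()] shared by the charts.
#' @param collapsed Logical; collapsed navigations render as an ideogram.
#' @return An object of class `Workspace`.
#' @export
workspace <- function(charts, region = NULL, collapsed = FALSE) {
  if (!is.null(region)) stopifnot(inherits(region, "GenomicRange"))
  structure(list(charts = charts, region = region, collapsed = collapsed),
            class = "Workspace")
}

chart_source_kind <- function(chart, sources) {
  # resolve a chart's measurements to (datasource, kind); genes tracks pull
  # gene models instead of a table
  if (chart$chart_type == "genes_track") {
    for (s in sources) if (length(s$genes)) {
      return(list(datasource_id = s$id, kind = "genes"))
    }
    stop("no datasource with gene models for chart '", chart$chart_id, "'",
         call. = FALSE)
  }
  for (s in sources) {
    for (m in s$measurements) {
      if (m$id %in% chart$measurement_ids) {
        return(list(datasource_id = s$id, kind = m$kind))
      }
    }
  }
  stop("unresolvable measurement for chart '", chart$chart_id, "': ",
       paste(chart$measurement_ids, collapse = ", "), call. = FALSE)
}

#' Render a workspace to per-chart SVG
#'
#' Fetches every chart's data through the shared [data_manager()] (so
#' shared measurements hit the underlying table once per region), renders
#' each chart, and returns the pieces the HTML exporter assembles. A
#' collapsed workspace issues zero data queries and returns one ideogram
#' per chromosome in view.
#'
#' @param ws A [workspace()].
#' @param dm A [data_manager()].
#' @param width_px Chart width.
#' @return A list with `svg` (named by chart id), `tables` (data used,
#'   named by chart id) and `layout` (from [layout_assign()]); for a
#'   collapsed workspace, `svg` holds the ideogram and `tables` is empty.
#' @export
render_workspace <- function(ws, dm, width_px = 800) {
  stopifnot(inherits(ws, "Workspace"), inherits(dm, "DataManager"))
  if (ws$collapsed) {
    if (is.null(ws$region)) stop("collapsed workspace needs a region", call. = FALSE)
    si <- NULL
    for (s in dm$sources) {
      row <- match(ws$region$chrom, s$seqinfo$chrom)
      if (!is.na(row)) { si <- s$seqinfo[row, ]; break }
    }
    if (is.null(si)) stop("unknown chromosome: ", ws$region$chrom, call. = FALSE)
    return(list(svg = list(ideogram = render_ideogram(si, ws$region, width_px)),
                tables = list(), layout = NULL))
  }
  svgs <- list()
  tables <- list()
  for (chart in ws$charts) {
    region <- chart$region_bound %||% ws$region
    loc <- chart_source_kind(chart, dm$sources)
    if (identical(loc$kind, "genes")) {
      src <- find_source(dm$sources, loc$datasource_id)
      data <- src$genes
      draw_region <- region %||% whole_genome_region(src)
      tables[[chart$chart_id]] <- data
    } else {
      tab <- dm_get_rows(dm, loc$datasource_id, loc$kind, region)
      data <- tab
      src <- find_source(dm$sources, loc$datasource_id)
      draw_region <- region %||% whole_genome_region(src)
      tables[[chart$chart_id]] <- tab
    }
    svgs[[chart$chart_id]] <- render_chart(chart, data, draw_region,
                                           width_px = width_px)
  }
  list(svg = svgs, tables = tables, layout = layout_assign(ws$charts))
}

whole_genome_region <- function(src) {
  # environment semantics: one spanning region on the first chromosome; a
  # true multi-chromosome concatenated axis is out of scope
  if (!nrow(src$seqinfo)) stop("datasource has no seqinfo", call. = FALSE)
  genomic_range(src$seqinfo$chrom[1L], 0, src$seqinfo$length[1L])
}

#' Export charts as a standalone self-contained HTML page
#'
#' The offline path: every chart's SVG and the columnar JSON of the exact
#' data it rendered are embedded in a single HTML document laid out on the
#' six-column grid, so the page opens with no network access and the data
#' can be recovered by parsing the embedded JSON blocks
#' (`<script type="application/json" data-chart-id=...>`). Output is
#' byte-identical across runs for identical inputs.
#'
#' @param charts List of [chart_spec()] objects.
#' @param sources List of [datasource()] objects.
#' @param region A [genomic_range()] all charts are rendered against.
#' @param out_path Output file path; `NULL` returns the HTML string only.
#' @param width_px Chart width.
#' @return The HTML text, invisibly.
#' @export
export_standalone_html <- function(charts, sources, region, out_path = NULL,
                                   width_px = 800) {
  stopifnot(inherits(region, "GenomicRange"))
  for (chart in charts) chart_source_kind(chart, sources)  # fail before writing
  dm <- data_manager(sources)
  ws <- workspace(charts, region = region)
  rendered <- render_workspace(ws, dm, width_px = width_px)
  lay <- rendered$layout
  cells <- character()
  for (chart in charts) {
    id <- chart$chart_id
    placement <- lay[lay$chart_id == id, ]
    tab <- rendered$tables[[id]]
    data_json <- if (inherits(tab, "ColumnTable")) {
      to_json_columnar(tab)
    } else {
      # genes track: embed the models as a JSON array
      as.character(jsonlite::toJSON(lapply(tab, function(g) {
        list(gene_name = g$gene_name, chr = g$range$chrom,
             start = g$range$start, end = g$range$end, strand = g$strand,
             exon_starts = g$exon_starts, exon_ends = g$exon_ends)
      }), digits = NA, auto_unbox = TRUE))
    }
    cells <- c(cells, paste0(
      '<div class="chart-cell" style="grid-row:', placement$row + 1,
      ';grid-column:', placement$col_start + 1, ' / span ',
      placement$col_span, ';">'),
      rendered$svg[[id]],
      paste0('<script type="application/json" data-chart-id="', id, '">'),
      data_json, "</script>", "</div>")
  }
  html <- paste(c(
    "<!DOCTYPE html>",
    '<html><head><meta charset="utf-8"/>',
    paste0("<title>", xml_escape(format(region)), "</title>"),
    "<style>",
    ".workspace{display:grid;grid-template-columns:repeat(6,1fr);gap:8px;}",
    ".chart-cell{overflow:hidden;}",
    "</style></head><body>",
    paste0('<div class="workspace" data-region="',
           xml_escape(format(region)), '">'),
    cells,
    "</div></body></html>"), collapse = "\n")
  if (!is.null(out_path)) {
    con <- file(out_path, open = "wb")
    writeBin(charToRaw(html), con)
    close(con)
  }
  invisible(html)
}

#' Recover the embedded data tables from an exported HTML page
#'
#' Parses the `application/json` blocks written by
#' [export_standalone_html()] back into `ColumnTable`s (gene-model blocks
#' are returned as parsed lists).
#'
#' @param html HTML text or a file path.
#' @return Named list by chart id.
#' @export
read_embedded_tables <- function(html) {
  if (length(html) == 1L && !grepl("\n", html, fixed = TRUE) &&
      file.exists(html)) {
    html <- paste(readLines(html, warn = FALSE), collapse = "\n")
  } else if (length(html) > 1L) {
    html <- paste(html, collapse = "\n")
  }
  pat <- '<script type="application/json" data-chart-id="([^"]+)">\n(.*?)\n</script>'
  m <- gregexpr(pat, html, perl = TRUE)
  starts <- m[[1]]
  out <- list()
  if (starts[1] == -1L) return(out)
  for (i in seq_along(starts)) {
    frag <- substr(html, starts[i], starts[i] + attr(m[[1]], "match.length")[i] - 1L)
    id <- sub(pat, "\\1", frag, perl = TRUE)
    body <- sub(pat, "\\2", frag, perl = TRUE)
    out[[id]] <- tryCatch(from_json_columnar(body),
                          error = function(e) jsonlite::fromJSON(body, simplifyDataFrame = FALSE))
  }
  out
}
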