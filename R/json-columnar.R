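#' Columnar JSON wire format
#'
#' Serializes a `ColumnTable` to the columnar JSON payload used by the
#' provider service and embedded in standalone HTML. The wire format's
#' required keys are `"chr"`, `"start"`, `"end"` plus a `"values"` object
#' mapping column names to arrays; optional string side columns travel
#' under `"strings"`. The wire key is `"chr"` while the internal field is
#' `chrom`; the serializer owns that mapping. Missing values become JSON
#' `null`; numbers keep full precision.
#'
#' @param tab A `ColumnTable`.
#' @return A single JSON string.
#' @examples
#' to_json_columnar(make_column_table("chr1", 0, 1, values = list(v = 5)))
#' @export
to_json_columnar <- function(tab) {
  stopifnot(inherits(tab, "ColumnTable"))
  payload <- list(
    chr = tab$chrom,
    start = tab$start,
    end = tab$end,
    values = tab$values
  )
  if (length(tab$strings)) payload$strings <- tab$strings
  # 17 significant digits: doubles survive the round trip bit-exactly
  as.character(jsonlite::toJSON(
    payload, null = "null", na = "null", digits = I(17), auto_unbox = FALSE))
}

#' Parse the columnar JSON wire format
#'
#' Inverse of [to_json_columnar()]. The keys `chr`, `start` and `end` are
#' required; a missing key raises a schema error naming it, and ragged
#' arrays fail validation.
#'
#' @param json A single JSON string.
#' @return A validated `ColumnTable`.
#' @export
from_json_columnar <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  for (key in c("chr", "start", "end")) {
    if (!key %in% names(x)) {
      stop("missing required key: ", key, call. = FALSE)
    }
  }
  as_num <- function(v) vapply(v, function(e) {
    if (is.null(e) || (length(e) == 1L && is.na(e))) NA_real_ else as.double(e)
  }, 0)
  fix <- function(v) if (is.list(v)) as_num(v) else as.double(v)
  values <- lapply(if (is.null(x$values)) list() else x$values, fix)
  strings <- lapply(if (is.null(x$strings)) list() else x$strings,
                    function(v) as.character(unlist(v)))
  make_column_table(
    chrom = as.character(unlist(x$chr)),
    start = if (length(x$start)) fix(x$start) else double(),
    end = if (length(x$end)) fix(x$end) else double(),
    values = values, strings = strings)
}

#' In-memory datasource
#'
#' Bundles everything the provider service needs to answer requests for one
#' dataset: tables keyed by measurement kind (`track` positional signal,
#' `feature` expression-like), gene models for the gene search and genes
#' track, chromosome sizes, and the measurement catalog. Storage is
#' in-memory from flat files; query semantics do not depend on the backend.
#'
#' @param id Datasource identifier.
#' @param tables Named list mapping measurement kind to `ColumnTable`
#'   (names from `c("track", "feature")`).
#' @param genes List of [gene_model()] objects.
#' @param seqinfo A [seq_info()] table.
#' @param measurements List of [measurement()] objects; every measurement id
#'   must name a value column in the table of its kind.
#' @return An object of class `Datasource`.
#' @export
datasource <- function(id, tables = list(), genes = list(),
                       seqinfo = seq_info(), measurements = list()) {
  stopifnot(is.character(id), length(id) == 1L)
  if (length(tables)) {
    if (is.null(names(tables)) || !all(names(tables) %in% c("track", "feature"))) {
      stop("tables must be named by kind: track, feature", call. = FALSE)
    }
    for (tb in tables) validate_column_table(tb)
  }
  for (m in measurements) {
    stopifnot(inherits(m, "Measurement"))
    tb <- tables[[m$kind]]
    if (is.null(tb) || !m$id %in% names(tb$values)) {
      stop("measurement '", m$id, "' has no value column in the '",
           m$kind, "' table", call. = FALSE)
    }
  }
  known <- seqinfo$chrom
  for (tb in tables) {
    extra <- setdiff(unique(tb$chrom), known)
    if (length(known) && length(extra)) {
      stop("table row chromosome not in seqinfo: ", extra[1L], call. = FALSE)
    }
  }
  structure(list(id = id, tables = tables, genes = genes,
                 seqinfo = seqinfo, measurements = measurements),
            class = "Datasource")
}

#' @export
print.Datasource <- function(x, ...) {
  cat("<Datasource> '", x$id, "': ", length(x$measurements),
      " measurement(s), ", length(x$genes), " gene(s), ",
      nrow(x$seqinfo), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Load datasources from a JSON config
#'
#' The config is a JSON object `{"datasources": [...]}` where each entry has
#' `id`, `format` (`"bed"`, `"bedgraph"`, `"gff3"`, `"feature_matrix"`),
#' `path`, an optional `kind` (default `"track"`, feature matrices default
#' to `"feature"`) and an optional `column_name` for bedGraph. Chromosome
#' sizes may be given as `{"seqinfo": {"chr1": 1000, ...}}` at the top level
#' or inferred from the data.
#'
#' @param path Path to the JSON config file.
#' @return A list of [datasource()] objects.
#' @export
load_sources_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$datasources)) stop("config has no 'datasources' key", call. = FALSE)
  si <- NULL
  if (!is.null(cfg$seqinfo)) {
    si <- seq_info(names(cfg$seqinfo), as.double(unlist(cfg$seqinfo)))
  }
  base_dir <- dirname(path)
  lapply(cfg$datasources, function(ds) {
    p <- ds$path
    if (!file.exists(p)) p <- file.path(base_dir, ds$path)
    genes <- list()
    tables <- list()
    measurements <- list()
    kind <- ds$kind
    if (identical(ds$format, "gff3")) {
      genes <- read_gff3(p)
    } else {
      tab <- switch(ds$format,
        bed = read_bed(p),
        bedgraph = read_bedgraph(p, column_name = ds$column_name %||% "score"),
        feature_matrix = read_feature_matrix(p),
        stop("unknown format: ", ds$format, call. = FALSE))
      if (is.null(kind)) {
        kind <- if (identical(ds$format, "feature_matrix")) "feature" else "track"
      }
      tables[[kind]] <- tab
      measurements <- lapply(names(tab$values), function(nm) {
        vals <- tab$values[[nm]]
        measurement(nm, datasource_id = ds$id, kind = kind,
                    value_min = suppressWarnings(min(vals, na.rm = TRUE)),
                    value_max = suppressWarnings(max(vals, na.rm = TRUE)))
      })
    }
    this_si <- si
    if (is.null(this_si)) {
      chroms <- unique(c(unlist(lapply(tables, `[[`, "chrom")),
                         vapply(genes, function(g) g$range$chrom, "")))
      ends <- vapply(chroms, function(ch) {
        m <- 0
        for (tb in tables) {
          sel <- tb$chrom == ch
          if (any(sel)) m <- max(m, tb$end[sel])
        }
        for (g in genes) if (g$range$chrom == ch) m <- max(m, g$range$end)
        m
      }, 0)
      this_si <- seq_info(chroms, pmax(ends, 1))
    }
    datasource(ds$id, tables = tables, genes = genes,
               seqinfo = this_si, measurements = measurements)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
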