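#' File format readers and writers
#'
#' Line-oriented parsers for the small flat-file dialects the toolkit
#' consumes: BED (3-5 columns), bedGraph, GFF3 gene models and a
#' tab-delimited feature-by-sample matrix. Parse errors always carry
#' 1-based line numbers. All readers produce tables that pass
#' [validate_column_table()].
#'
#' @name readers
NULL

read_lines_arg <- function(x) {
  # accepts a path or a character vector of lines (a "stream")
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

is_header_line <- function(line) {
  grepl("^(track|browser|#)", line) || !nzchar(trimws(line))
}

parse_num <- function(x, what, lineno) {
  v <- suppressWarnings(as.double(x))
  bad <- which(is.na(v) & !(x %in% c("NA", "")))
  # values literally "NA" stay NA by convention (feature matrix); coordinates
  # are checked separately by callers
  if (length(bad)) {
    stop(what, " is not numeric at line ", lineno[bad[1L]], ": '",
         x[bad[1L]], "'", call. = FALSE)
  }
  v
}

parse_coord <- function(x, what, lineno) {
  v <- suppressWarnings(as.double(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad)) {
    stop(what, " is not an integer at line ", lineno[bad[1L]], ": '",
         x[bad[1L]], "'", call. = FALSE)
  }
  v
}

#' Read a BED file
#'
#' BED3 through BED5; `track`/`browser`/comment header lines are skipped.
#' Coordinates are kept 0-based half-open as in the file. Column 4 (name)
#' becomes the string column `"name"` when present; column 5 (score)
#' becomes the value column `"score"`. Columns beyond 5 are ignored.
#'
#' @param x Path, single string with embedded newlines, or character vector
#'   of lines.
#' @return A `ColumnTable`.
#' @export
read_bed <- function(x) {
  lines <- read_lines_arg(x)
  lineno <- seq_along(lines)
  keep <- !vapply(lines, is_header_line, logical(1), USE.NAMES = FALSE)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) return(make_column_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("expected >= 3 tab-separated fields at line ",
         lineno[which(nf < 3L)[1L]], call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), "start", lineno)
  end <- parse_coord(vapply(fields, `[[`, "", 3L), "end", lineno)
  values <- list()
  strings <- list()
  if (all(nf >= 4L)) {
    strings$name <- vapply(fields, `[[`, "", 4L)
  }
  if (all(nf >= 5L)) {
    values$score <- parse_num(vapply(fields, `[[`, "", 5L), "score", lineno)
  }
  make_column_table(chrom, start, end, values = values, strings = strings)
}

#' Write a BED file
#'
#' Inverse of [read_bed()]: emits BED3, BED4 (`name` string column present)
#' or BED5 (`name` and `score` present).
#'
#' @param tab A `ColumnTable`.
#' @param path Output path; if `NULL`, the lines are returned invisibly
#'   without writing.
#' @return Character vector of lines, invisibly.
#' @export
write_bed <- function(tab, path = NULL) {
  stopifnot(inherits(tab, "ColumnTable"))
  cols <- list(tab$chrom, format_pos(tab$start), format_pos(tab$end))
  if (!is.null(tab$strings$name)) {
    cols <- c(cols, list(tab$strings$name))
    if (!is.null(tab$values$score)) {
      cols <- c(cols, list(format_val(tab$values$score)))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a bedGraph file
#'
#' Four columns: chrom, start, end, value. The single value column is named
#' by `column_name`.
#'
#' @inheritParams read_bed
#' @param column_name Name for the value column.
#' @return A `ColumnTable` with one value column.
#' @export
read_bedgraph <- function(x, column_name = "score") {
  lines <- read_lines_arg(x)
  lineno <- seq_along(lines)
  keep <- !vapply(lines, is_header_line, logical(1), USE.NAMES = FALSE)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) {
    return(make_column_table(values = stats::setNames(list(double()), column_name)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("expected 4 tab-separated fields at line ",
         lineno[which(nf < 4L)[1L]], call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), "start", lineno)
  end <- parse_coord(vapply(fields, `[[`, "", 3L), "end", lineno)
  raw <- vapply(fields, `[[`, "", 4L)
  v <- suppressWarnings(as.double(raw))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop("value is not numeric at line ", lineno[bad[1L]], ": '",
         raw[bad[1L]], "'", call. = FALSE)
  }
  make_column_table(chrom, start, end,
                    values = stats::setNames(list(v), column_name))
}

#' Write a bedGraph file
#'
#' @param tab A `ColumnTable` with at least one value column.
#' @param path Output path, or `NULL` to only return the lines.
#' @param column Value column to write; default the first.
#' @return Character vector of lines, invisibly.
#' @export
write_bedgraph <- function(tab, path = NULL, column = names(tab$values)[1L]) {
  stopifnot(inherits(tab, "ColumnTable"))
  if (is.null(column) || !column %in% names(tab$values)) {
    stop("no such value column: ", column, call. = FALSE)
  }
  lines <- paste(tab$chrom, format_pos(tab$start), format_pos(tab$end),
                 format_val(tab$values[[column]]), sep = "\t")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features; exons are attached to their gene via
#' the `Parent` attribute (matching the gene's `ID`). GFF3's 1-based closed
#' coordinates are converted to 0-based half-open (`start - 1`, `end`
#' unchanged), so internal span length equals GFF `end - start + 1`.
#'
#' @inheritParams read_bed
#' @return A list of [gene_model()] objects.
#' @export
read_gff3 <- function(x) {
  lines <- read_lines_arg(x)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("expected 9 tab-separated fields at line ",
         lineno[which(nf < 9L)[1L]], call. = FALSE)
  }
  type <- vapply(fields, `[[`, "", 3L)
  attr_field <- vapply(fields, `[[`, "", 9L)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  genes <- list()          # id -> list(...)
  gene_order <- character()
  for (i in which(type == "gene")) {
    f <- fields[[i]]
    id <- get_attr(f[9], "ID")
    if (is.na(id)) stop("gene without ID attribute at line ", lineno[i],
                        call. = FALSE)
    nm <- get_attr(f[9], "Name")
    genes[[id]] <- list(
      gene_name = if (is.na(nm)) id else nm,
      chrom = f[1],
      start = parse_coord(f[4], "start", lineno[i]) - 1,
      end = parse_coord(f[5], "end", lineno[i]),
      strand = if (f[7] %in% c("+", "-")) f[7] else ".",
      exon_starts = double(), exon_ends = double())
    gene_order <- c(gene_order, id)
  }
  for (i in which(type == "exon")) {
    f <- fields[[i]]
    parent <- get_attr(f[9], "Parent")
    if (is.na(parent) || is.null(genes[[parent]])) {
      stop("exon with unresolvable Parent at line ", lineno[i], call. = FALSE)
    }
    g <- genes[[parent]]
    es <- parse_coord(f[4], "start", lineno[i]) - 1
    ee <- parse_coord(f[5], "end", lineno[i])
    if (es < g$start || ee > g$end) {
      stop("exon outside span of gene '", g$gene_name, "' at line ",
           lineno[i], call. = FALSE)
    }
    g$exon_starts <- c(g$exon_starts, es)
    g$exon_ends <- c(g$exon_ends, ee)
    genes[[parent]] <- g
  }
  lapply(gene_order, function(id) {
    g <- genes[[id]]
    gene_model(g$gene_name, genomic_range(g$chrom, g$start, g$end),
               g$strand, g$exon_starts, g$exon_ends)
  })
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()] up to coordinate convention (writes 1-based
#' closed).
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path, or `NULL`.
#' @return Character vector of lines, invisibly.
#' @export
write_gff3 <- function(genes, path = NULL) {
  lines <- "##gff-version 3"
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    id <- paste0("gene", i)
    lines <- c(lines, paste(
      g$range$chrom, "genotracks", "gene",
      format_pos(g$range$start + 1), format_pos(g$range$end),
      ".", g$strand, ".",
      paste0("ID=", id, ";Name=", g$gene_name), sep = "\t"))
    for (j in seq_along(g$exon_starts)) {
      lines <- c(lines, paste(
        g$range$chrom, "genotracks", "exon",
        format_pos(g$exon_starts[j] + 1), format_pos(g$exon_ends[j]),
        ".", g$strand, ".",
        paste0("ID=", id, ".e", j, ";Parent=", id), sep = "\t"))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a feature-by-sample matrix
#'
#' Tab-delimited with header `chrom start end feature_name <sample...>`:
#' one numeric value column per sample, with the feature name carried as a
#' string side column. `NA` cells become missing values.
#'
#' @inheritParams read_bed
#' @return A `ColumnTable` with one value column per sample.
#' @export
read_feature_matrix <- function(x) {
  lines <- read_lines_arg(x)
  if (!length(lines)) stop("empty feature matrix: no header", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4L ||
      !identical(header[1:4], c("chrom", "start", "end", "feature_name"))) {
    stop("feature matrix header must start with chrom\tstart\tend\tfeature_name",
         call. = FALSE)
  }
  samples <- header[-(1:4)]
  if (anyDuplicated(samples)) {
    stop("duplicate sample name: ", samples[duplicated(samples)][1L],
         call. = FALSE)
  }
  body <- lines[-1L]
  lineno <- seq_along(body) + 1L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- lineno[keep]
  if (!length(body)) {
    return(make_column_table(
      values = stats::setNames(rep(list(double()), length(samples)), samples),
      strings = list(feature_name = character())))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    stop("expected ", length(header), " fields at line ",
         lineno[which(nf != length(header))[1L]], call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), "start", lineno)
  end <- parse_coord(vapply(fields, `[[`, "", 3L), "end", lineno)
  feature_name <- vapply(fields, `[[`, "", 4L)
  values <- lapply(seq_along(samples), function(j) {
    parse_num(vapply(fields, `[[`, "", 4L + j), samples[j], lineno)
  })
  names(values) <- samples
  make_column_table(chrom, start, end, values = values,
                    strings = list(feature_name = feature_name))
}

#' Write a feature-by-sample matrix
#'
#' Inverse of [read_feature_matrix()]; missing values are written as `NA`.
#'
#' @param tab A `ColumnTable` with a `feature_name` string column.
#' @param path Output path, or `NULL`.
#' @return Character vector of lines, invisibly.
#' @export
write_feature_matrix <- function(tab, path = NULL) {
  stopifnot(inherits(tab, "ColumnTable"))
  if (is.null(tab$strings$feature_name)) {
    stop("table has no feature_name column", call. = FALSE)
  }
  header <- paste(c("chrom", "start", "end", "feature_name",
                    names(tab$values)), collapse = "\t")
  cols <- c(list(tab$chrom, format_pos(tab$start), format_pos(tab$end),
                 tab$strings$feature_name),
            lapply(tab$values, format_val))
  lines <- c(header, if (ct_nrow(tab)) do.call(paste, c(cols, sep = "\t")))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

format_val <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, "")
  out
}
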