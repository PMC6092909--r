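#' Genomic coordinate types
#'
#' All coordinates in this package are 0-based half-open `[start, end)`:
#' adjacent intervals share a boundary but never overlap, and
#' `end - start` is the span length in bases. BED and bedGraph inputs are
#' already in this convention; GFF3 (1-based closed) is converted on read.
#'
#' @name coordinates
NULL

#' Create a genomic range
#'
#' A chromosome plus a half-open `[start, end)` span. This is the unit of
#' navigation, querying and brushing throughout the package.
#'
#' @param chrom Chromosome name (single string). Names are matched exactly;
#'   no `"chr1"`/`"1"` aliasing is performed.
#' @param start 0-based start position (non-negative).
#' @param end End position (exclusive); must satisfy `end >= start`.
#' @return An object of class `GenomicRange`.
#' @examples
#' genomic_range("chr1", 0, 1000)
#' @export
genomic_range <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.double(start)
  end <- as.double(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("start and end must be single non-missing numbers", call. = FALSE)
  }
  if (start != floor(start) || end != floor(end)) {
    stop("start and end must be whole numbers", call. = FALSE)
  }
  if (start < 0) stop("start must be >= 0, got ", start, call. = FALSE)
  if (end < start) {
    stop("end (", end, ") must be >= start (", start, ")", call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "GenomicRange")
}

#' Parse a region string
#'
#' Accepts the usual browser syntax `chr:start-end`, e.g. `"chr1:0-1000000"`.
#' Coordinates are taken verbatim as 0-based half-open.
#'
#' @param text Region string.
#' @return A [genomic_range()].
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse region '", text, "'; expected chr:start-end",
         call. = FALSE)
  }
  genomic_range(m[2], as.double(m[3]), as.double(m[4]))
}

#' @export
format.GenomicRange <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom, format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))
}

#' @export
print.GenomicRange <- function(x, ...) {
  cat("<GenomicRange> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Span of a genomic range in bases
#' @param region A [genomic_range()].
#' @return `end - start`.
#' @export
range_span <- function(region) {
  stopifnot(inherits(region, "GenomicRange"))
  region$end - region$start
}

#' Do two half-open ranges overlap?
#'
#' `[0,10)` and `[10,20)` do not overlap. Ranges on different chromosomes
#' never overlap.
#'
#' @param a,b [genomic_range()] objects.
#' @return Logical scalar.
#' @export
ranges_overlap <- function(a, b) {
  stopifnot(inherits(a, "GenomicRange"), inherits(b, "GenomicRange"))
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Chromosome size table
#'
#' Holds chromosome names and lengths; needed for genome-wide views,
#' navigation clamping and ideograms.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Positive integer vector of chromosome lengths in bases.
#' @return A data.frame with class `SeqInfo` and columns `chrom`, `length`.
#' @export
seq_info <- function(chrom = character(), length = double()) {
  chrom <- as.character(chrom)
  length <- as.double(length)
  if (base::length(chrom) != base::length(length)) {
    stop("chrom and length must have equal lengths", call. = FALSE)
  }
  if (anyDuplicated(chrom)) stop("duplicate chromosome names", call. = FALSE)
  if (any(is.na(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("SeqInfo", "data.frame"))
}

#' Describe one queryable data column
#'
#' A measurement is the metadata for a single value column of a datasource:
#' where it lives, whether it is positional signal (`track`) or a
#' per-feature quantity such as expression (`feature`), and its value range
#' for axis scaling.
#'
#' @param id Measurement identifier (must match a value column name).
#' @param name Display label; defaults to `id`.
#' @param datasource_id Identifier of the owning datasource.
#' @param kind `"track"` or `"feature"`.
#' @param value_min,value_max Optional value bounds (`value_min <= value_max`).
#' @param annotation Optional named character vector of extra metadata.
#' @return An object of class `Measurement`.
#' @export
measurement <- function(id, name = id, datasource_id = "", kind = c("track", "feature"),
                        value_min = NA_real_, value_max = NA_real_,
                        annotation = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  value_min <- as.double(value_min)
  value_max <- as.double(value_max)
  if (!is.na(value_min) && !is.na(value_max) && value_min > value_max) {
    stop("value_min must be <= value_max", call. = FALSE)
  }
  structure(list(id = id, name = name, datasource_id = datasource_id,
                 kind = kind, value_min = value_min, value_max = value_max,
                 annotation = annotation),
            class = "Measurement")
}

#' Gene model with exon structure
#'
#' @param gene_name Gene symbol.
#' @param range A [genomic_range()] spanning the gene.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param exon_starts,exon_ends Parallel vectors of exon coordinates
#'   (0-based half-open), sorted, non-overlapping, within `range`.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_name, range, strand = ".",
                       exon_starts = double(), exon_ends = double()) {
  stopifnot(inherits(range, "GenomicRange"))
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  exon_starts <- as.double(exon_starts)
  exon_ends <- as.double(exon_ends)
  if (length(exon_starts) != length(exon_ends)) {
    stop("gene ", gene_name, ": exon_starts and exon_ends lengths differ",
         call. = FALSE)
  }
  if (length(exon_starts)) {
    if (any(exon_ends < exon_starts)) {
      stop("gene ", gene_name, ": exon end before start", call. = FALSE)
    }
    if (any(exon_starts < range$start) || any(exon_ends > range$end)) {
      stop("gene ", gene_name, ": exon outside gene span", call. = FALSE)
    }
    o <- order(exon_starts, exon_ends)
    exon_starts <- exon_starts[o]
    exon_ends <- exon_ends[o]
    if (length(exon_starts) > 1L &&
        any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
      stop("gene ", gene_name, ": overlapping exons", call. = FALSE)
    }
  }
  structure(list(gene_name = gene_name, range = range, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends),
            class = "GeneModel")
}
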