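#' Build an interval index over a ColumnTable
#'
#' Rows are grouped per chromosome and held in an `IRanges` nested
#' containment structure so that repeated overlap queries (every pan, zoom
#' and brush triggers one) avoid a full scan. Half-open `[start, end)`
#' coordinates are mapped to the 1-based closed ranges `IRanges` expects
#' (`start + 1`, `end`); zero-width rows therefore never match, which is
#' the correct half-open semantics.
#'
#' @param tab A `ColumnTable`.
#' @return An object of class `RangeIndex` referencing `tab`.
#' @export
build_index <- function(tab) {
  validate_column_table(tab)
  idx <- list()
  if (ct_nrow(tab)) {
    by_chrom <- split(seq_len(ct_nrow(tab)), tab$chrom)
    idx <- lapply(by_chrom, function(rows) {
      list(rows = rows,
           ranges = IRanges::IRanges(start = tab$start[rows] + 1,
                                     end = tab$end[rows]))
    })
  }
  structure(list(by_chrom = idx, table = tab), class = "RangeIndex")
}

#' Query an interval index
#'
#' Returns the indices of all rows whose half-open span intersects the
#' query region. Adjacent ranges do not overlap: with rows `[0,10)` and
#' `[10,20)`, the query `[10,11)` hits only the second. An unknown
#' chromosome yields an empty result, not an error.
#'
#' @param index A [build_index()] result.
#' @param region A [genomic_range()].
#' @return Integer row indices, ascending by `(start, end, index)`.
#' @export
overlap_query <- function(index, region) {
  stopifnot(inherits(index, "RangeIndex"), inherits(region, "GenomicRange"))
  entry <- index$by_chrom[[region$chrom]]
  if (is.null(entry) || region$end <= region$start) return(integer())
  q <- IRanges::IRanges(start = region$start + 1, end = region$end)
  hits <- IRanges::findOverlaps(q, entry$ranges)
  rows <- entry$rows[S4Vectors::subjectHits(hits)]
  tab <- index$table
  rows[order(tab$start[rows], tab$end[rows], rows)]
}

#' Bin a region and summarize signal per bin
#'
#' The workhorse of server-side summarization: the query region is tiled
#' into `n_bins` contiguous half-open bins and each value column is reduced
#' per bin. When the span is at least `n_bins` bases, bins have integer
#' width `floor(span / n_bins)` and the last bin absorbs the remainder;
#' for narrower spans boundaries fall at `floor(b * span / n_bins)` so the
#' bins still exactly tile the region. A row contributes its value once to
#' every bin its span intersects, with no length weighting (the
#' `"wmean"` statistic offers an overlap-length-weighted mean instead).
#' Empty bins have count 0 and value `NA` (serialized as `null`).
#'
#' @param tab A `ColumnTable`.
#' @param region A [genomic_range()] with `end > start`.
#' @param n_bins Number of bins; the default 2000 matches the provider's
#'   summarization contract.
#' @param stat One of `"mean"`, `"min"`, `"max"`, `"sum"`, `"count"`,
#'   `"wmean"`.
#' @return An object of class `BinnedTable` with fields `region`, `n_bins`,
#'   `bin_starts`, `bin_ends`, `values` (column -> numeric, `NA` for empty
#'   bins) and `counts` (column -> non-missing contribution counts).
#' @export
summarize_region <- function(tab, region, n_bins = 2000,
                             stat = c("mean", "min", "max", "sum", "count", "wmean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(tab, "ColumnTable"), inherits(region, "GenomicRange"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  span <- range_span(region)
  if (span <= 0) stop("region must have end > start", call. = FALSE)

  if (span >= n_bins) {
    w <- span %/% n_bins
    bin_starts <- region$start + (seq_len(n_bins) - 1L) * w
    bin_ends <- c(bin_starts[-1L], region$end)   # last bin absorbs remainder
  } else {
    bin_starts <- region$start + floor((seq_len(n_bins) - 1L) * span / n_bins)
    bin_ends <- c(bin_starts[-1L], region$end)
  }

  hit <- rows_in_region(tab, region)
  empty_col <- function() rep(NA_real_, n_bins)
  values <- stats::setNames(lapply(names(tab$values), function(n) empty_col()),
                            names(tab$values))
  counts <- stats::setNames(lapply(names(tab$values), function(n) rep(0, n_bins)),
                            names(tab$values))
  res <- structure(list(region = region, n_bins = n_bins,
                        bin_starts = bin_starts, bin_ends = bin_ends,
                        values = values, counts = counts,
                        stat = stat),
                   class = "BinnedTable")
  if (!length(hit) || !length(tab$values)) return(res)

  s <- pmax(tab$start[hit], region$start)
  e <- pmin(tab$end[hit], region$end)
  # bin index of a position: rightmost bin whose start <= pos
  pos_bin <- function(pos) findInterval(pos, bin_starts)
  first_bin <- pos_bin(s)
  last_bin <- pos_bin(pmax(e - 1, s))   # e-1: last base covered (half-open)
  nb <- last_bin - first_bin + 1L
  # expand row -> (row, bin) incidences; most rows hit a single bin
  row_rep <- rep(seq_along(hit), nb)
  bin_of <- unlist(lapply(seq_along(hit), function(i) first_bin[i]:last_bin[i]),
                   use.names = FALSE)
  if (stat == "wmean") {
    ov <- pmin(e[row_rep], bin_ends[bin_of]) - pmax(s[row_rep], bin_starts[bin_of])
    ov <- pmax(ov, 0)
  }
  for (nm in names(tab$values)) {
    v <- tab$values[[nm]][hit][row_rep]
    ok <- !is.na(v)
    b <- bin_of[ok]
    vv <- v[ok]
    cnt <- tabulate(b, nbins = n_bins)
    res$counts[[nm]] <- as.double(cnt)
    if (!length(vv)) next
    out <- rep(NA_real_, n_bins)
    agg <- switch(stat,
      mean = {
        s1 <- rowsum_vec(vv, b, n_bins); s1 / ifelse(cnt > 0, cnt, NA)
      },
      sum = rowsum_vec(vv, b, n_bins, zero_as_na = TRUE),
      count = as.double(cnt) * ifelse(cnt > 0, 1, NA),
      min = group_extreme(vv, b, n_bins, min),
      max = group_extreme(vv, b, n_bins, max),
      wmean = {
        wts <- ov[ok]
        sw <- rowsum_vec(wts, b, n_bins)
        swv <- rowsum_vec(vv * wts, b, n_bins)
        ifelse(sw > 0, swv / sw, ifelse(cnt > 0, rowsum_vec(vv, b, n_bins) / cnt, NA))
      })
    out[cnt > 0] <- agg[cnt > 0]
    res$values[[nm]] <- out
  }
  res
}

rowsum_vec <- function(v, g, n, zero_as_na = FALSE) {
  out <- rep(0, n)
  rs <- rowsum(v, g)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

group_extreme <- function(v, g, n, fn) {
  out <- rep(NA_real_, n)
  sp <- split(v, g)
  out[as.integer(names(sp))] <- vapply(sp, fn, 0)
  out
}

#' @export
print.BinnedTable <- function(x, ...) {
  cat("<BinnedTable> ", format(x$region), ", ", x$n_bins, " bins (",
      x$stat, ")\n", sep = "")
  invisible(x)
}

#' Convert a BinnedTable to a ColumnTable
#'
#' Bins become rows on the region's chromosome; useful for rendering the
#' summarized path with the same chart code as raw data.
#'
#' @param bt A `BinnedTable`.
#' @param drop_empty Drop bins with all-zero counts (default `FALSE`).
#' @return A `ColumnTable`.
#' @export
binned_to_table <- function(bt, drop_empty = FALSE) {
  stopifnot(inherits(bt, "BinnedTable"))
  keep <- seq_len(bt$n_bins)
  if (drop_empty && length(bt$counts)) {
    any_count <- Reduce(`+`, bt$counts) > 0
    keep <- which(any_count)
  }
  make_column_table(rep(bt$region$chrom, length(keep)),
                    bt$bin_starts[keep], bt$bin_ends[keep],
                    values = lapply(bt$values, `[`, keep))
}

#' Serialize a BinnedTable to JSON
#'
#' Same columnar schema as [to_json_columnar()] plus a `counts` object.
#'
#' @param bt A `BinnedTable`.
#' @return A JSON string.
#' @export
binned_to_json <- function(bt) {
  stopifnot(inherits(bt, "BinnedTable"))
  payload <- list(chr = rep(bt$region$chrom, bt$n_bins),
                  start = bt$bin_starts, end = bt$bin_ends,
                  values = bt$values, counts = bt$counts)
  as.character(jsonlite::toJSON(payload, null = "null", na = "null",
                                digits = I(17), auto_unbox = FALSE))
}

#' Group overlapping data points into one visual object per pixel
#'
#' Rendering optimization for feature plots: each in-region row is mapped
#' to the pixel column of its interval midpoint,
#' `floor((mid - start) / span * width)`, clamped to `[0, width - 1]`;
#' rows landing on the same pixel form one visual object whose
#' representative value per column is the group mean (missing values
#' skipped). Consequently a chart never renders more objects than it has
#' pixel columns.
#'
#' @param tab A `ColumnTable`.
#' @param region A [genomic_range()].
#' @param plot_width_px Plot width in pixels (>= 1).
#' @return A list of groups ordered by `pixel_x`, each a list with
#'   `pixel_x` (0-based), `rows` (member row indices) and `values`
#'   (named representative values).
#' @export
group_overlapping_points <- function(tab, region, plot_width_px) {
  stopifnot(inherits(tab, "ColumnTable"), inherits(region, "GenomicRange"))
  plot_width_px <- as.integer(plot_width_px)
  if (is.na(plot_width_px) || plot_width_px < 1L) {
    stop("plot_width_px must be >= 1", call. = FALSE)
  }
  hit <- rows_in_region(tab, region)
  if (!length(hit)) return(list())
  mid <- (tab$start[hit] + tab$end[hit]) / 2
  span <- range_span(region)
  px <- floor((mid - region$start) / span * plot_width_px)
  px <- pmin(pmax(px, 0), plot_width_px - 1L)
  groups <- split(hit, px)
  lapply(names(groups), function(p) {
    rows <- groups[[p]]
    vals <- vapply(tab$values, function(col) {
      v <- col[rows]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
    list(pixel_x = as.integer(p), rows = rows, values = vals)
  })
}
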