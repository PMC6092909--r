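#' Aggregate value columns row-wise
#'
#' Client-side style aggregation across measurements: e.g. collapse ten
#' tumor samples into one mean column to compare against the normal-sample
#' mean. Missing values are skipped; a row where all named columns are
#' missing yields a missing result. Input columns are retained.
#'
#' @param tab A `ColumnTable`.
#' @param columns Names of value columns to aggregate.
#' @param stat One of `"mean"`, `"min"`, `"max"`, `"sum"`, `"median"`.
#' @param out_name Name for the new column (must be unused).
#' @return The table with one extra value column `out_name`.
#' @export
aggregate_columns <- function(tab, columns,
                              stat = c("mean", "min", "max", "sum", "median"),
                              out_name) {
  stat <- match.arg(stat)
  stopifnot(inherits(tab, "ColumnTable"))
  missing_cols <- setdiff(columns, names(tab$values))
  if (length(missing_cols)) {
    stop("unknown column: ", missing_cols[1L], call. = FALSE)
  }
  if (out_name %in% c(names(tab$values), names(tab$strings))) {
    stop("column '", out_name, "' already exists", call. = FALSE)
  }
  m <- do.call(cbind, tab$values[columns])
  fn <- switch(stat, mean = mean, min = min, max = max, sum = sum,
               median = stats::median)
  out <- apply(m, 1L, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) NA_real_ else fn(row)
  })
  if (!ct_nrow(tab)) out <- double()
  tab$values[[out_name]] <- as.double(out)
  validate_column_table(tab)
  tab
}

#' Pairwise distances between matrix rows
#'
#' Distance metrics offered by the heatmap clustering settings. Rows with
#' missing entries are mean-imputed per column first (documented policy;
#' the source material is silent on missing data). `one_minus_pearson`
#' is `1 - cor(x, y)`; a constant row makes the correlation undefined and
#' raises an error.
#'
#' @param m Numeric matrix (rows are the items to cluster).
#' @param metric `"euclidean"`, `"one_minus_pearson"` or `"manhattan"`.
#' @return A symmetric base-`matrix` of distances with zero diagonal,
#'   dimnames from `rownames(m)`.
#' @export
pairwise_distances <- function(m, metric = c("euclidean", "one_minus_pearson",
                                             "manhattan")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (any(rowSums(!is.na(m)) == 0)) stop("all-missing row", call. = FALSE)
  if (anyNA(m)) {
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      m[, j] <- col
    }
  }
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(m, method = "euclidean")),
    manhattan = as.matrix(stats::dist(m, method = "manhattan")),
    one_minus_pearson = {
      if (any(apply(m, 1L, stats::sd) == 0)) {
        stop("constant row: correlation undefined", call. = FALSE)
      }
      1 - stats::cor(t(m))
    })
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Classic bottom-up clustering over a precomputed distance matrix with
#' single, complete or average (UPGMA) linkage, as used to order heatmap
#' rows and draw the dendrogram. Ties are resolved deterministically:
#' among equal-distance candidate pairs, the pair whose (lexicographically
#' smallest member label, then second label) is smallest merges first, so
#' output is reproducible across platforms.
#'
#' @param d Symmetric distance matrix (a base matrix or `dist`); item
#'   labels from dimnames, defaulting to `item1..itemN`.
#' @param linkage `"single"`, `"complete"` or `"average"`.
#' @return An object of class `Dendrogram` with fields `merge` (hclust-style
#'   `(n-1) x 2` matrix, negative entries are leaves), `height` (merge
#'   distances, non-decreasing for these linkages), `labels` and
#'   `leaf_order` (left-to-right labels; the smaller-keyed child is drawn
#'   left).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0)) {
    stop("invalid distance matrix", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))

  # active clusters: id > 0 = merge step, id < 0 = leaf -i
  active <- as.list(-seq_len(n))          # member leaf ids (negative)
  key <- labels                           # lexicographic tie-break key
  size <- rep(1, n)
  cur <- d
  alive <- rep(TRUE, n)
  slot_id <- -seq_len(n)                  # hclust-style id of cluster in slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- double(n - 1L)
  children <- vector("list", n - 1L)      # ordered (left, right) slot keys

  node_key <- vector("list", 2L * n)      # key per hclust id (offset n+1)
  kidx <- function(id) id + n + 1L        # map id in [-n, n-1] to index
  for (i in seq_len(n)) node_key[[kidx(-i)]] <- labels[i]

  left_right <- matrix(0L, n - 1L, 2L)    # ids of (left, right) children

  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    best <- NULL
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      if (ai == length(idx)) break
      js <- idx[(ai + 1L):length(idx)]
      dij <- cur[i, js]
      for (t in seq_along(js)) {
        j <- js[t]
        cand_keys <- sort(c(key[i], key[j]))
        cand <- list(dist = dij[t], i = i, j = j, k1 = cand_keys[1], k2 = cand_keys[2])
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             (cand$k1 < best$k1 || (cand$k1 == best$k1 && cand$k2 < best$k2)))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    height[step] <- best$dist
    merge[step, ] <- sort(c(slot_id[i], slot_id[j]))
    # left child = smaller key, for a deterministic left-to-right leaf order
    if (key[i] <= key[j]) {
      left_right[step, ] <- c(slot_id[i], slot_id[j])
    } else {
      left_right[step, ] <- c(slot_id[j], slot_id[i])
    }
    # Lance-Williams update of distances to the merged cluster, stored in slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      di <- cur[i, others]; dj <- cur[j, others]
      newd <- switch(linkage,
        single = pmin(di, dj),
        complete = pmax(di, dj),
        average = (size[i] * di + size[j] * dj) / (size[i] + size[j]))
      cur[i, others] <- newd
      cur[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    alive[j] <- FALSE
    key[i] <- min(key[i], key[j])
    slot_id[i] <- step
    node_key[[kidx(step)]] <- key[i]
  }

  # leaf order: in-order traversal, left child first
  walk <- function(id) {
    if (id < 0L) return(labels[-id])
    c(walk(left_right[id, 1L]), walk(left_right[id, 2L]))
  }
  leaf_order <- walk(n - 1L)

  structure(list(merge = merge, height = height, labels = labels,
                 leaf_order = leaf_order, left_right = left_right,
                 linkage = linkage),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat("<Dendrogram> ", length(x$labels), " leaves, ", x$linkage,
      " linkage; order: ", paste(x$leaf_order, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are `parent height - child height` (leaves have height 0),
#' so path lengths reproduce merge heights.
#'
#' @param dend A `Dendrogram`.
#' @return Newick string terminated by `;`.
#' @export
dendrogram_to_newick <- function(dend) {
  stopifnot(inherits(dend, "Dendrogram"))
  node_h <- function(id) if (id < 0L) 0 else dend$height[id]
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 10)
  build <- function(id, parent_h) {
    bl <- fmt(parent_h - node_h(id))
    if (id < 0L) return(paste0(dend$labels[-id], ":", bl))
    kids <- dend$left_right[id, ]
    paste0("(", build(kids[1L], node_h(id)), ",",
           build(kids[2L], node_h(id)), "):", bl)
  }
  root <- nrow(dend$merge)
  kids <- dend$left_right[root, ]
  h <- dend$height[root]
  paste0("(", build(kids[1L], h), ",", build(kids[2L], h), ");")
}

#' Serialize a dendrogram to a JSON tree
#'
#' Nested objects `{height, children: [...]}` with `{label}` leaves, the
#' shape the heatmap renderer consumes.
#'
#' @param dend A `Dendrogram`.
#' @return A JSON string.
#' @export
dendrogram_to_json <- function(dend) {
  stopifnot(inherits(dend, "Dendrogram"))
  build <- function(id) {
    if (id < 0L) return(list(label = dend$labels[-id], height = 0))
    kids <- dend$left_right[id, ]
    list(height = dend$height[id],
         children = list(build(kids[1L]), build(kids[2L])))
  }
  as.character(jsonlite::toJSON(build(nrow(dend$merge)), auto_unbox = TRUE,
                                digits = NA))
}
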