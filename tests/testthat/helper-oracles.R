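# Shared helpers: small random-table generators and independent brute-force
# oracles. Oracles are deliberately written as plain loops/scans, separate
# from the package's own code paths.

random_table <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         max_width = 200, n_cols = 2, na_frac = 0) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  values <- stats::setNames(lapply(seq_len(n_cols), function(j) {
    v <- stats::rnorm(n)
    if (na_frac > 0) v[stats::runif(n) < na_frac] <- NA
    v
  }), paste0("v", seq_len(n_cols)))
  make_column_table(chrom, start, start + width, values = values)
}

# independent linear-scan overlap oracle (half-open)
oracle_overlap <- function(tab, region) {
  hits <- integer()
  for (i in seq_len(ct_nrow(tab))) {
    if (tab$chrom[i] == region$chrom &&
        tab$start[i] < region$end && tab$end[i] > region$start &&
        tab$end[i] > tab$start[i]) {
      hits <- c(hits, i)
    }
  }
  hits[order(tab$start[hits], tab$end[hits], hits)]
}

# brute-force per-bin grouped statistic over explicit bin boundaries
oracle_bin_stat <- function(tab, region, bin_starts, bin_ends, col,
                            stat = "mean") {
  n_bins <- length(bin_starts)
  out <- rep(NA_real_, n_bins)
  cnt <- rep(0, n_bins)
  for (b in seq_len(n_bins)) {
    vals <- double()
    for (i in seq_len(ct_nrow(tab))) {
      if (tab$chrom[i] != region$chrom) next
      s <- max(tab$start[i], region$start)
      e <- min(tab$end[i], region$end)
      if (e <= s) next
      if (s < bin_ends[b] && e > bin_starts[b]) {
        v <- tab$values[[col]][i]
        if (!is.na(v)) vals <- c(vals, v)
      }
    }
    cnt[b] <- length(vals)
    if (length(vals)) {
      out[b] <- switch(stat, mean = mean(vals), sum = sum(vals),
                       min = min(vals), max = max(vals),
                       count = length(vals))
    }
  }
  list(value = out, count = cnt)
}

# naive agglomerative reference: recompute inter-cluster distance from the
# original matrix at every step (O(n^3)), no Lance-Williams update
oracle_hclust_heights <- function(d, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- double()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        pair_d <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dist_ij <- switch(linkage, single = min(pair_d),
                          complete = max(pair_d),
                          average = mean(pair_d))
        if (dist_ij < best_d) {
          best_d <- dist_ij
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# minimum spanning tree edge weights (Prim), for the single-linkage property
oracle_mst_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  weights <- double()
  while (sum(in_tree) < n) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    w <- min(sub)
    weights <- c(weights, w)
    j <- which(!in_tree)[which(sub == w, arr.ind = TRUE)[1L, 2L]]
    in_tree[j] <- TRUE
  }
  sort(weights)
}

count_visual_objects <- function(svg) {
  m <- gregexpr('class="visual-object"', svg, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

make_test_sources <- function(cfg = fixture_config()) {
  genome <- make_genome(cfg)
  sig <- make_signal_track(cfg, "chr1")
  pk <- make_peaks(cfg, "chr1")
  gm <- make_gene_models(cfg, "chr1")
  ex <- make_expression(cfg)
  list(
    signal = datasource("signal", tables = list(track = sig$table),
                        genes = gm$genes, seqinfo = genome,
                        measurements = list(measurement("signal", kind = "track",
                                                        datasource_id = "signal"))),
    peaks = datasource("peaks", tables = list(track = pk$table),
                       seqinfo = genome,
                       measurements = list(measurement("score", kind = "track",
                                                       datasource_id = "peaks"))),
    expression = datasource("expression", tables = list(feature = ex$table),
                            seqinfo = genome,
                            measurements = lapply(names(ex$table$values),
                              function(s) measurement(s, kind = "feature",
                                                      datasource_id = "expression"))),
    raw = list(signal = sig, peaks = pk, genes = gm, expression = ex))
}

# spawn a provider in a background Rscript, wait until it answers
start_test_server <- function(sources_code, port, max_requests,
                              idle_timeout = 60) {
  code <- paste0(
    ".libPaths(", paste(deparse(.libPaths()), collapse = ""), ")\n",
    "library(genotracks)\n",
    sources_code, "\n",
    "serve(sources, port = ", port, ", max_requests = ", max_requests,
    ", idle_timeout = ", idle_timeout, ", quiet = TRUE)\n")
  f <- tempfile(fileext = ".R")
  writeLines(code, f)
  system2("Rscript", shQuote(f), wait = FALSE,
          stdout = tempfile(), stderr = tempfile())
  for (i in 1:100) {
    Sys.sleep(0.15)
    r <- tryCatch(
      suppressWarnings(request_http(data_request(0, "get_measurements"),
                                    port = port, timeout = 2)),
      error = function(e) NULL)
    if (!is.null(r)) return(TRUE)
  }
  FALSE
}
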