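test_that("handle_request serves every action with the envelope contract", {
  srcs <- make_test_sources(fixture_config(seed = 14))
  sources <- srcs[c("signal", "peaks", "expression")]

  si <- handle_request(data_request(1, "get_seqinfos",
                                    list(datasource = "signal")), sources)
  expect_true(si$success)
  expect_equal(si$request_id, 1L)
  expect_equal(si$payload$seqinfo,
               list(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6))

  ms <- handle_request(data_request(2, "get_measurements"), sources)
  expect_true(ms$success)
  ids <- vapply(ms$payload$measurements, `[[`, "", "id")
  expect_true(all(c("signal", "score", "sample01") %in% ids))

  # get_rows in an empty region: success with an empty payload
  rows0 <- handle_request(data_request(3, "get_rows",
    list(datasource = "peaks", region = "chr2:0-100")), sources)
  expect_true(rows0$success)
  expect_length(rows0$payload$start, 0L)

  rows <- handle_request(data_request(4, "get_rows",
    list(datasource = "signal", region = "chr1:0-5000",
         measurement = "signal")), sources)
  expect_true(rows$success)
  expect_equal(length(rows$payload$start), 5L)

  gene_name <- sources$signal$genes[[1]]$gene_name
  sg <- handle_request(data_request(5, "search_genes",
    list(datasource = "signal",
         query = tolower(substr(gene_name, 1, 6)))), sources)
  expect_true(sg$success)
  expect_true(gene_name %in%
                vapply(sg$payload$genes, `[[`, "", "gene_name"))

  # error paths: success=false, never an R error
  bad1 <- handle_request(data_request(6, "get_rows",
    list(datasource = "nope", region = "chr1:0-1")), sources)
  expect_false(bad1$success)
  expect_match(bad1$error, "unknown datasource")
  bad2 <- handle_request(data_request(7, "get_rows",
    list(datasource = "signal", region = "chr1_0_1")), sources)
  expect_false(bad2$success)
  bad3 <- handle_request(data_request(8, "get_summary",
    list(datasource = "signal", region = "chr1:0-100",
         measurement = "nope")), sources)
  expect_false(bad3$success)
  expect_match(bad3$error, "unknown measurement")
})

test_that("get_summary payload equals a direct summarize_region call", {
  srcs <- make_test_sources(fixture_config(seed = 25))
  sources <- srcs["signal"]
  region <- genomic_range("chr1", 10000, 600000)
  resp <- handle_request(data_request(9, "get_summary",
    list(datasource = "signal", region = format(region), n_bins = 100)),
    sources)
  expect_true(resp$success)
  direct <- summarize_region(srcs$raw$signal$table, region, 100)
  expect_equal(unlist(resp$payload$values$signal), direct$values$signal)
  expect_equal(unlist(resp$payload$counts$signal), direct$counts$signal)
  expect_equal(length(resp$payload$start), 100L)
})

test_that("HTTP transport is transparent and survives many requests", {
  port <- 20000L + (Sys.getpid() %% 10000L)
  sources_code <- '
    cfg <- fixture_config(seed = 14)
    sig <- make_signal_track(cfg, "chr1")
    genome <- make_genome(cfg)
    sources <- list(datasource("signal", tables = list(track = sig$table),
      seqinfo = genome,
      measurements = list(measurement("signal", kind = "track",
                                      datasource_id = "signal"))))'
  n_requests <- 24L
  expect_true(start_test_server(sources_code, port,
                                max_requests = n_requests + 2L))

  cfg <- fixture_config(seed = 14)
  sig <- make_signal_track(cfg, "chr1")
  genome <- make_genome(cfg)
  sources <- list(datasource("signal", tables = list(track = sig$table),
    seqinfo = genome,
    measurements = list(measurement("signal", kind = "track",
                                    datasource_id = "signal"))))

  reqs <- list(
    data_request(1, "get_seqinfos", list(datasource = "signal")),
    data_request(2, "get_measurements"),
    data_request(3, "get_rows", list(datasource = "signal",
                                     region = "chr1:0-20000")),
    data_request(4, "get_summary", list(datasource = "signal",
                                        region = "chr1:0-1000000",
                                        n_bins = 50)))
  # every action: HTTP response equals in-process handle_request
  for (req in reqs) {
    over_http <- request_http(req, port = port)
    over_http$http_status <- NULL
    direct <- jsonlite::fromJSON(
      jsonlite::toJSON(handle_request(req, sources), null = "null",
                       na = "null", digits = NA, auto_unbox = TRUE),
      simplifyVector = TRUE, simplifyDataFrame = FALSE,
      simplifyMatrix = FALSE)
    expect_equal(over_http, direct)
  }

  # a burst of identical summary requests: all correct (stateless handler)
  ref <- request_http(reqs[[4]], port = port)
  for (k in seq_len(n_requests - length(reqs) - 1L)) {
    got <- request_http(reqs[[4]], port = port)
    expect_equal(got$payload$values, ref$payload$values)
  }
})

test_that("malformed JSON body gets HTTP 400", {
  port <- 20000L + ((Sys.getpid() + 137L) %% 10000L)
  expect_true(start_test_server(
    'sources <- list(datasource("empty", seqinfo = seq_info("chr1", 100)))',
    port, max_requests = 3L))
  con <- socketConnection("127.0.0.1", port, blocking = TRUE, open = "a+b",
                          timeout = 10)
  body <- "this is not json"
  writeBin(charToRaw(paste0(
    "POST / HTTP/1.1\r\nHost: x\r\nContent-Length: ", nchar(body),
    "\r\nConnection: close\r\n\r\n", body)), con)
  flush(con)
  status <- readLines(con, n = 1L, warn = FALSE)
  close(con)
  expect_match(status, "400")
})

test_that("data manager: shared measurements query the table once", {
  srcs <- make_test_sources(fixture_config(seed = 30))
  dm <- data_manager(srcs[c("signal", "peaks")])
  region <- genomic_range("chr1", 0, 200000)
  # three charts sharing one measurement: a single underlying query
  charts <- list(chart_spec("a", "line_track", "signal"),
                 chart_spec("b", "blocks_track", "signal"),
                 chart_spec("c", "scatter_plot", "signal"))
  ws <- workspace(charts, region = region)
  rendered <- render_workspace(ws, dm)
  expect_equal(dm$query_count, 1L)
  expect_length(rendered$svg, 3L)

  # a region change is a new query; re-render of the same region is not
  ws2 <- workspace(charts, region = navigate(region, "pan_right"))
  render_workspace(ws2, dm)
  expect_equal(dm$query_count, 2L)
  render_workspace(ws2, dm)
  expect_equal(dm$query_count, 2L)
})

test_that("collapsed navigation issues zero data queries", {
  srcs <- make_test_sources(fixture_config(seed = 30))
  dm <- data_manager(srcs[c("signal", "peaks")])
  ws <- workspace(list(chart_spec("a", "line_track", "signal")),
                  region = genomic_range("chr1", 0, 100000),
                  collapsed = TRUE)
  out <- render_workspace(ws, dm)
  expect_equal(dm$query_count, 0L)
  expect_named(out$svg, "ideogram")
  expect_match(out$svg$ideogram, "region-highlight")
})

test_that("standalone HTML export embeds SVG + JSON and round trips", {
  srcs <- make_test_sources(fixture_config(seed = 18))
  sources <- srcs[c("signal", "peaks")]
  region <- genomic_range("chr1", 0, 150000)
  charts <- list(chart_spec("line1", "line_track", "signal"),
                 chart_spec("peaks1", "blocks_track", "score"))
  f <- tempfile(fileext = ".html")
  html <- export_standalone_html(charts, sources, region, out_path = f)

  # one SVG and one JSON block per chart
  expect_length(gregexpr("<svg", html, fixed = TRUE)[[1]], 2L)
  expect_length(gregexpr('type="application/json"', html, fixed = TRUE)[[1]],
                2L)
  # no external references: self-contained
  expect_false(grepl("http://|https://|src=", gsub(
    "http://www.w3.org/2000/svg", "", html, fixed = TRUE)))

  # embedded JSON parses back to the rendered tables
  emb <- read_embedded_tables(f)
  expect_true(ct_identical(
    emb$line1,
    subset_rows(srcs$raw$signal$table,
                rows_in_region(srcs$raw$signal$table, region))))
  expect_true(ct_identical(
    emb$peaks1,
    subset_rows(srcs$raw$peaks$table,
                rows_in_region(srcs$raw$peaks$table, region))))

  # byte-identical re-export
  f2 <- tempfile(fileext = ".html")
  export_standalone_html(charts, sources, region, out_path = f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # unresolvable measurement: error before writing
  f3 <- tempfile(fileext = ".html")
  expect_error(export_standalone_html(
    list(chart_spec("x", "line_track", "nonexistent")), sources, region,
    out_path = f3), "unresolvable")
  expect_false(file.exists(f3))

  # one-chart export: exactly one SVG and one JSON block
  html1 <- export_standalone_html(charts[1], sources, region)
  expect_length(gregexpr("<svg", html1, fixed = TRUE)[[1]], 1L)
  expect_length(gregexpr('type="application/json"', html1, fixed = TRUE)[[1]],
                1L)
})

test_that("CLI subcommands run end to end", {
  dir <- tempfile("cli")
  suppressMessages(run_cli(c("make-fixtures", "--seed", "7", "--out", dir)))
  expect_true(file.exists(file.path(dir, "sources.json")))

  bins_out <- tempfile(fileext = ".json")
  suppressMessages(run_cli(c("summarize",
    "--input", file.path(dir, "chr1_signal.bedgraph"),
    "--region", "chr1:0-1000000", "--bins", "250", "--stat", "mean",
    "--out", bins_out)))
  payload <- jsonlite::fromJSON(bins_out)
  expect_length(payload$start, 250L)

  svg_out <- tempfile(fileext = ".svg")
  suppressMessages(run_cli(c("render", "--chart", "line",
    "--input", file.path(dir, "chr1_signal.bedgraph"),
    "--region", "chr1:0-500000", "--out", svg_out)))
  expect_silent(xml2::read_xml(paste(readLines(svg_out), collapse = "\n")))

  ws_path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    region = "chr1:0-200000", sources = file.path(dir, "sources.json"),
    charts = list(list(chart_id = "c1", chart_type = "line_track",
                       measurement_ids = "signal"))),
    ws_path, auto_unbox = TRUE)
  html_out <- tempfile(fileext = ".html")
  suppressMessages(run_cli(c("export-html", "--workspace", ws_path,
                             "--out", html_out)))
  expect_length(read_embedded_tables(html_out), 1L)

  expect_error(run_cli(c("summarize", "--region", "chr1:0-10")), "--input")
  expect_error(run_cli("frobnicate"), "unknown command")
})
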